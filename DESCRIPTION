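Package: etongue
Title: Digital Fingerprinting of Multichannel Electronic-Tongue Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for AI-assisted chemical sensing with
    potentiometric sensor arrays (electronic tongues). Multichannel
    voltage recordings are concatenated into spectrum-like vectors,
    encoded as Gramian Angular Field images (GAF and the
    intensity-weighted GAF* variant), featurized with a pluggable frozen
    image-feature extractor, reduced with principal component analysis
    and classified with lightweight model heads (random forest, linear
    discriminant analysis, k-nearest neighbours, support vector machine,
    extra trees, gradient-boosted trees). Includes repeated stratified
    five-fold resampling, leave-one-class-out validation with mid-level
    relabeling, leave-one-product-out validation, ward-linkage
    agglomerative clustering scored by the adjusted Rand index, pixel-wise
    mixup image augmentation with a few-shot training harness, and a
    seeded synthetic sensor-array simulator so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    mclust,
    png,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    viridisLite,
    xgboost
Suggests:
    class,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
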