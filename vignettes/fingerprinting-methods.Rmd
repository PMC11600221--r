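---
title: "Gramian fingerprinting of electronic-tongue recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gramian fingerprinting of electronic-tongue recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etongue)
```

## The problem

A potentiometric electronic tongue is an array of cross-sensitive
electrodes immersed in a liquid; each electrode responds to many analytes
at once, so no single channel identifies a sample — the *pattern* across
channels does. The measurement protocol here is a 100 s dwell in a
reference liquid followed by 60 s in the test liquid, with 15 differential
voltages sampled at 1 Hz. `etongue` turns such recordings into
image "fingerprints", featurizes the images with a frozen extractor,
and trains lightweight classifiers on principal-component scores, so that
one sensing platform can be reconfigured for many recognition tasks
(wine identification, protein products, sugar type and level, milk
protein source) from a handful of measurements.

## From voltages to images

Per measurement, the pipeline is:

1. **Test window.** Only the 60 s test-phase samples are kept
   (`extract_test_window()`); the reference dwell serves at most for
   optional baseline correction (`baseline_subtract()`, off by default
   because raw test-phase signals are encoded).
2. **Concatenation.** The 15 channel traces are joined channel-major into
   one spectrum-like vector of 15 × 60 = 900 points
   (`concatenate_channels()`). The order is ascending channel index and is
   part of the encoding's definition, since the Gram matrix is not
   permutation-invariant.
3. **PAA.** Piecewise aggregate approximation (`paa_reduce()`) brings the
   900-point series down to the working resolution M (96 by default, 224
   for the larger backbone contracts). Downsampling happens on the 1-D
   series *before* the Gram matrix, so the cost is O(M²) and the Gram
   structure is computed at the target resolution rather than resampled
   afterwards.
4. **Normalization.** Per-measurement min–max mapping onto [−1, 1]
   (`minmax_normalize()`). A constant signal maps to zeros (rather than
   erroring) so degenerate fixtures flow through. Dataset-level bounds can
   be supplied instead when a common amplitude scale should be kept.
5. **Angular encoding.** With φᵢ = arccos(xᵢ), the Gramian Angular
   (Summation) Field is Gᵢⱼ = cos(φᵢ + φⱼ) (`gaf()`), equivalently
   xᵢxⱼ − √(1−xᵢ²)√(1−xⱼ²). G is symmetric, bounded in [−1, 1], with
   diagonal 2xᵢ² − 1; temporal self-correlation becomes image texture. The
   difference-form variant (sin-based) is deliberately out of scope.
6. **GAF\*.** Min–max normalization erases amplitude, which for sensors
   carries chemical information. `gaf_star()` rescales column j of G by a
   weight derived from the raw (pre-normalization) PAA-reduced signal.
   Weights are the raw signal min–max mapped to [0, 1]: weighting by raw
   volts would blow the matrix out of the renderable [−1, 1] range, so the
   volt-scale option exists only behind `scale_weights = FALSE`. Whether
   the original scheme weighted before or after pixel rescaling is not
   documented; weighting the matrix first is the choice here.
7. **Rendering.** `render_image()` maps [min, max] affinely to 0…255
   (round-half-to-even; constant matrices render black) and replicates the
   gray plane to 3 channels. A fixed perceptually-uniform colormap mode
   exists because published fingerprints are colored, but the exact
   published mapping is unknown, so grayscale replication is the default.

## Featurization and heads

`builtin_extract()` is the default frozen extractor: a deterministic
1280-dimensional embedding (8 × 8 grid of per-cell mean/sd/min/max plus
the lowest 32 × 32 block of the image's 2-D DCT). It is *not* a learned
model — it is a transparent stand-in honoring the same contract as a
pooled vision-backbone output (pure function of pixels, fixed dimension,
order 10³), chosen so the full pipeline runs offline and deterministically.
The twelve pretrained backbone configurations (MobileNetV2, ResNet, ViT
and BeiT families at 96/224/384 px) are registered behind the same
interface (`extractor_spec()`, `backbone_extract()`); without weights the
adapter raises a capability error and the builtin extractor is used.

Embeddings are reduced by centered PCA (`fit_pca()`), always fitted on
training rows only; every validation protocol refits the basis per split,
so held-out data can never leak into the representation. A global-fit
variant is possible by fitting on the full set explicitly, but it is not
what the harnesses do. Heads (`head_spec()`): random forest (50 trees),
LDA, 3-NN, SVM (RBF defaults), extra trees (100 trees, no bootstrap) and
gradient-boosted trees (100 rounds, η = 0.3, depth 6). KNN ties are broken
by the nearest neighbour's label, which makes 3-NN deterministic; the
stochastic heads take an explicit seed. The `"random"` head predicts
uniformly among training classes and anchors chance level (1/7 ≈ 14.3 %
for seven classes, 1/6 ≈ 16.7 % for six).

## Validation protocols

* **Repeated stratified resampling** (`evaluate_kfold()`): 50 repetitions
  of a random stratified 80 %/20 % train/test split. With 10 replicates
  per class, plain 5-fold cross-validation repeated 10 times would be an
  alternative reading; fresh stratified 80/20 resamples guarantee every
  class appears in training every repetition, which is the property the
  protocol needs.
* **Sugar leave-one-class-out** (`evaluate_sugar_locov()`): the four
  extreme cells (each sugar × {2.5, 10} % w/w) are held out in turn; the
  5 % mid-level is relabeled *low* when the held-out class is 2.5 % and
  *high* when it is 10 %, so training always covers glucose/sucrose ×
  low/high. Predictions are pooled: 4 × 10 = 40 test measurements, one
  pooled error ⇒ 97.5 %.
* **Milk leave-one-product-out** (`evaluate_milk_lopo()`): every
  commercial product is held out in turn and its protein source predicted
  among five classes. Each source class must own ≥ 2 products, otherwise
  the held-out product's class would vanish from training and the
  protocol errors out.
* **Clustering** (`cluster_fingerprints()`): Ward-linkage agglomerative
  clustering (Euclidean distance, `ward.D2`, equivalent to scikit-learn's
  `ward`) on PCA scores with a predetermined group count, scored by the
  Adjusted Rand Index.
* **Few-shot** (`fewshot_experiment()`): k ∈ {3, 5, 7} shots per class
  for training, everything else as test, 50 random splits, 10 principal
  components (the reduced training size cannot support 20). Both
  conditions (with/without mixup augmentation) run on identical splits and
  are compared with a pooled-variance two-sided t-test, significance at
  p < 0.05.

## Mixup augmentation

Synthetic training images are convex pixel-wise combinations
s = a·p + (1−a)·q of a primary image p of class Cᵢ and a donor q of a
different class, labeled Cᵢ, with a + b = 1 and a > 0.5
(`mix_images()`). `augment_training_set()` tops every class up to 50
training instances (real shots plus synthetics; 3 shots ⇒ 47 synthetics
per class). Donor class and both instances are drawn uniformly per
synthetic sample — the donor distribution is unspecified in the original
scheme beyond "varying the type and instance", and uniform is the
assumption-free choice. The default mixing ratio is a/b = 0.85/0.15, the
middle of the supported grid (0.95/0.05 … 0.75/0.25), since the ratio has
been reported not to matter much. Mixed pixels are rounded half-to-even;
geometric augmentation (rotation, mirroring) is deliberately excluded
because the fingerprint's geometry *is* the signal.

## The synthetic sensor simulator

Real electronic-tongue data cannot ship with the package, so
`simulate_task_data()` generates datasets with the statistical structure
the pipeline assumes. Channel c of a recording follows

    v_c(t) = b_c + drift·t + Δ_c·(1 − exp(−t_test/τ)) + ε,  ε ~ N(0, σ²)

with static per-channel baselines b_c ~ N(0, 0.05 V), an exponential
approach (τ = 10 s) to a class-specific steady-state shift Δ during the
test phase, slow linear drift (10⁻⁵ V/s) and white noise. This is the
simplest response shape matching observed reference-to-test transitions
of such arrays; it makes no electrochemical claims (no Nernstian slopes,
no cross-sensitivity chemistry, no rinse phase).

Chosen scales, and why:

* **Archetype shifts** Δ ~ separation × N(0, (50 mV)²) per channel —
  steady-state perturbations of tens of millivolts are typical when a
  potentiometric array moves from mineral water to a complex liquid.
* **Noise** σ = 2 mV and **replicate jitter** N(0, (5 mV)²) on Δ —
  sub-percent relative noise plus visible replicate scatter, the regime
  in which well-separated classes classify near-perfectly while
  `separation = 0` stays exactly at chance.
* **Sugar levels** scale Δ by 2.5/5/10 ratios (0.25, 0.5, 1.0), embedding
  concentration ordering so mid-level relabeling is meaningful. A held-out
  10 % cell is then an extrapolation beyond its training surrogate (5 %
  labeled *high*), which is why the sugar protocol is the hardest of the
  synthetic tasks.
* **Products** within a class share the class archetype plus a per-product
  offset ~ N(0, (0.4 × separation × 50 mV)²) — smaller than between-class
  distances, so leave-one-product-out is solvable but non-trivial.
* **Layouts** mirror the study designs: 7 × 10 wine, 6 × 10 protein,
  2 × 3 × 10 sugar, milk as 12 products over 5 source classes
  (almond 2, cow 2, soy 2, oat 3, pea 3 — the published roster lists one
  class twice and omits one; this reading gives every class ≥ 2 products,
  which the protocol requires) × 5 replicates. The beverage clustering
  layout uses 32 products (coffee 8, juice 9, water 8, wine 7) × 5
  replicates; the original collection totalled 150 instances with
  unstated per-product counts, so a uniform count (160 instances) is used
  and the mismatch accepted.

All randomness flows from one root seed; replicate seeds are derived
deterministically from (seed, class, product, replicate), so identical
configurations reproduce datasets bit for bit.

What the simulator does *not* emulate: session-to-session sensor drift,
electrode aging and hysteresis, correlated (non-white) noise, and
channel cross-talk. Passing tests on synthetic data therefore demonstrate
the pipeline's correctness and statistical behaviour — chance calibration,
leakage-freedom, monotone response to class separation — not field
performance on real liquids, which depends on sensor chemistry the
simulator deliberately ignores.

## Numerical choices and degenerate inputs

* arccos inputs are clipped within a 1e−12 tolerance; violations beyond
  1e−9 raise a domain error rather than being silently clipped, because
  they indicate a broken normalization upstream.
* PAA segment boundaries use floor indices `(⌊(m−1)N/M⌋, ⌊mN/M⌋]`; the
  global mean is preserved exactly when M divides N.
* Constant signals normalize to zeros; constant matrices render black;
  constant GAF* weight inputs become unit weights.
* Rounding to pixel range is round-half-to-even everywhere (R's `round`),
  documented because augmentation reproducibility depends on it.
* Two zero-variance accuracy distributions compare at p = 1 when their
  means agree (p = 0 otherwise) instead of erroring inside `t.test`.
* Sub-unit problem sizes in the harnesses: per-class test counts are
  `max(1, floor(0.2 n))`, so 5 instances per class is the protocol minimum.

## Problem sizes used in the shipped checks

The packaged tests run the full study layouts (70/60/60/60/160
measurements) at a 96 px working resolution with the builtin extractor,
50-repetition resampling for the accuracy properties, 250 repetitions for
the chance-level estimates in the acceptance script (a Monte Carlo
precision choice for a quantity whose exact value is 1/n_classes), and
3-shot few-shot runs at 50 repetitions. Unit tests use a reduced 3 × 6
layout with 4 channels and 48 px images to keep per-operation checks
fast; the reduced sizes change nothing structural.

## Known limitations

* The builtin extractor is linear-algebraic texture summarization; it will
  not reproduce the inductive biases of pretrained CNN/ViT embeddings, and
  real-data rankings across the twelve backbones cannot be studied without
  their weights.
* GAF encodes a normalized 1-D series; channel concatenation order is a
  convention, and cross-channel correlations appear only as off-diagonal
  blocks of the Gram matrix, not as a learned relation.
* The simulator's Gaussian, uncorrelated noise makes synthetic tasks
  easier than field data at matched separation; absolute synthetic
  accuracies should not be read as expected field accuracies.
* The milk and clustering rosters involve documented reading choices where
  the published layouts are ambiguous (see above).
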