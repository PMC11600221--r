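#' Feature-extractor specifications
#'
#' An extractor turns a rendered fingerprint into a fixed-length embedding
#' and is always a pure function of the pixels (frozen weights — nothing is
#' ever trained). The package ships one `builtin-deterministic` extractor
#' (see [builtin_extract()]); the named pretrained vision backbones the
#' field uses (MobileNetV2, ResNet, ViT, BeiT families) are registered as
#' `external-backbone` configuration entries consumed through
#' [backbone_extract()], so the pipeline is runnable without any downloaded
#' weights.
#'
#' @param name Extractor name: `"builtin"` or one of
#'   `names(backbone_registry())`.
#' @return A list of class `"extractor_spec"` with fields `name`,
#'   `input_resolution`, `output_dim` and `kind`.
#' @export
#' @examples
#' extractor_spec("builtin")
#' extractor_spec("vit_base_384")$input_resolution
extractor_spec <- function(name = "builtin") {
  if (identical(name, "builtin")) {
    return(structure(list(name = "builtin", input_resolution = NA_integer_,
                          output_dim = 1280L, kind = "builtin-deterministic"),
                     class = "extractor_spec"))
  }
  reg <- backbone_registry()
  if (!name %in% names(reg)) {
    stop_invalid(sprintf("unknown extractor '%s'", name))
  }
  entry <- reg[[name]]
  structure(list(name = name, input_resolution = entry$input_resolution,
                 output_dim = entry$output_dim, kind = "external-backbone"),
            class = "extractor_spec")
}

#' @rdname extractor_spec
#' @export
backbone_registry <- function() {
  list(
    mobilenetv2_35_96   = list(input_resolution = 96L,  output_dim = 1280L),
    mobilenetv2_100_224 = list(input_resolution = 224L, output_dim = 1280L),
    mobilenetv2_140_224 = list(input_resolution = 224L, output_dim = 1792L),
    resnet18_224        = list(input_resolution = 224L, output_dim = 512L),
    resnet50_224        = list(input_resolution = 224L, output_dim = 2048L),
    resnet101_224       = list(input_resolution = 224L, output_dim = 2048L),
    vit_base_224        = list(input_resolution = 224L, output_dim = 768L),
    vit_large_224       = list(input_resolution = 224L, output_dim = 1024L),
    vit_base_384        = list(input_resolution = 384L, output_dim = 768L),
    beit_base_224       = list(input_resolution = 224L, output_dim = 768L),
    beit_large_224      = list(input_resolution = 224L, output_dim = 1024L),
    beit_base_384       = list(input_resolution = 384L, output_dim = 768L)
  )
}

# orthonormal DCT-II basis matrices, cached per size
dct_basis <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      k <- 0:(n - 1)
      d <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
      d[1, ] <- d[1, ] / sqrt(2)
      cache[[key]] <- d
    }
    cache[[key]]
  }
})

#' Built-in deterministic image-feature extractor
#'
#' A download-free frozen extractor honoring the same contract as a pooled
#' pretrained-backbone output: a pure, deterministic function of the pixels
#' producing a fixed 1280-dimensional embedding. The embedding concatenates,
#' in this order:
#' \enumerate{
#'   \item per-cell mean, standard deviation, min and max of the gray plane
#'     over an 8 x 8 grid of cells (row-major cells, the four statistics
#'     contiguous per cell; 256 values);
#'   \item the lowest-frequency 32 x 32 block of the 2-D discrete cosine
#'     transform of the gray plane, flattened column-major (1024 values).
#' }
#' The gray plane is the channel mean rescaled to `[0, 1]`. The image side
#' must be a multiple of 8 and at least 32.
#'
#' @param img A `"rendered_image"` (H x W x 3, values 0..255).
#' @return A numeric vector of length 1280.
#' @export
builtin_extract <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]
  if (h != dim(img)[2]) stop_invalid("image must be square")
  if (h %% 8 != 0 || h < 32) {
    stop_invalid("builtin extractor needs a square side >= 32 and divisible by 8")
  }
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)
  cell <- h / 8
  stats <- numeric(256)
  idx <- 1L
  for (i in seq_len(8)) {
    rows <- ((i - 1) * cell + 1):(i * cell)
    for (j in seq_len(8)) {
      v <- gray[rows, ((j - 1) * cell + 1):(j * cell)]
      stats[idx:(idx + 3L)] <- c(mean(v), sd(as.vector(v)), min(v), max(v))
      idx <- idx + 4L
    }
  }
  d <- dct_basis(h)
  coeffs <- d %*% gray %*% t(d)
  c(stats, as.vector(coeffs[1:32, 1:32]))
}

#' Extract an embedding with a pretrained vision backbone
#'
#' Adapter contract for the external pretrained models. No backbone weights
#' ship with the package, so in this installation the call always raises a
#' capability error directing the user to the builtin extractor; the
#' argument checks (resolution match, known name) are live either way, so a
#' future adapter plugs in without interface changes.
#'
#' @param img A `"rendered_image"`.
#' @param spec An `"extractor_spec"` of kind `external-backbone`.
#' @return A numeric embedding of length `spec$output_dim` (when an adapter
#'   is available).
#' @export
backbone_extract <- function(img, spec) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (identical(spec$kind, "builtin-deterministic")) {
    return(builtin_extract(img))
  }
  if (dim(img)[1] != spec$input_resolution) {
    stop_invalid(sprintf("image resolution %d does not match extractor '%s' (expects %d)",
                         dim(img)[1], spec$name, spec$input_resolution))
  }
  stop_capability(sprintf(
    "no weights available for backbone '%s'; use extractor_spec(\"builtin\") instead",
    spec$name
  ))
}

#' Featurize every fingerprint image in a dataset
#'
#' Applies the chosen frozen extractor to each rendered image. Embeddings
#' are memoized by image content hash within the session, so repeated
#' protocol runs over the same images (e.g. 50-repetition resampling) pay
#' the extraction cost once.
#'
#' @param data A tibble with an `image` list column
#'   (from [encode_fingerprints()]).
#' @param extractor An extractor name or `"extractor_spec"`.
#' @param cache Use the content-hash memo cache (default `TRUE`).
#' @return The input tibble with an added `embedding` list column.
#' @export
extract_features <- function(data, extractor = "builtin", cache = TRUE) {
  stopifnot(is.data.frame(data), "image" %in% names(data))
  spec <- if (inherits(extractor, "extractor_spec")) extractor else extractor_spec(extractor)
  emb <- purrr::map(data$image, function(img) {
    if (cache) cached_extract(img, spec) else backbone_extract(img, spec)
  })
  dplyr::mutate(data, embedding = emb)
}

.extract_cache <- new.env(parent = emptyenv())

cached_extract <- function(img, spec) {
  key <- paste(spec$name, rlang::hash(unclass(img)), sep = "|")
  hit <- .extract_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- backbone_extract(img, spec)
  .extract_cache[[key]] <- out
  out
}

embedding_matrix <- function(data) {
  stopifnot("embedding" %in% names(data))
  do.call(rbind, data$embedding)
}

#' Fit a PCA reduction on training embeddings
#'
#' Centered (unscaled) principal component analysis, fitted on training
#' embeddings only — the basis never sees held-out data, so the validation
#' protocols are leakage-free by construction. Typical component counts in
#' this pipeline are 5, 10, 15, 20 or 25.
#'
#' @param train A FingerprintSet tibble (with `embedding`) or an n x d
#'   numeric matrix.
#' @param k Number of components, `k <= min(n, d)`.
#' @return A list of class `"pca_model"` with `n_components`, `rotation`
#'   (d x k), `explained_variance_ratio` and `center`.
#' @export
fit_pca <- function(train, k) {
  x <- if (is.data.frame(train)) embedding_matrix(train) else as.matrix(train)
  k <- check_count(k, "k")
  if (k > min(dim(x))) {
    stop_invalid(sprintf("k = %d exceeds min(n = %d, d = %d)", k, nrow(x), ncol(x)))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(n_components = k, rotation = pc$rotation,
                 explained_variance_ratio = evr[seq_len(k)],
                 center = pc$center),
            class = "pca_model")
}

#' Project embeddings onto a fitted PCA basis
#'
#' @param model A `"pca_model"` from [fit_pca()].
#' @param newdata A FingerprintSet tibble (with `embedding`) or an n x d
#'   matrix with d matching the fit.
#' @return If `newdata` is a tibble, the tibble with an added `scores` list
#'   column; otherwise an n x k score matrix.
#' @export
transform_pca <- function(model, newdata) {
  stopifnot(inherits(model, "pca_model"))
  x <- if (is.data.frame(newdata)) embedding_matrix(newdata) else as.matrix(newdata)
  if (ncol(x) != nrow(model$rotation)) {
    stop_invalid(sprintf("embeddings have %d dims but model expects %d",
                         ncol(x), nrow(model$rotation)))
  }
  scores <- sweep(x, 2L, model$center, "-") %*% model$rotation
  if (is.data.frame(newdata)) {
    dplyr::mutate(newdata, scores = lapply(seq_len(nrow(scores)),
                                           function(i) scores[i, ]))
  } else {
    scores
  }
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         explained_variance_ratio = x$explained_variance_ratio)
}
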