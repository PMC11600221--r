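#' Polar (angular) representation of a normalized signal
#'
#' Maps each element of a `[-1, 1]` signal to an angle `phi_i = arccos(x_i)`
#' in `[0, pi]` and a radius `r_i = i / N`. Values may stray outside the
#' closed interval by at most `1e-9` (they are clipped); larger excursions
#' raise an error because they signal a normalization bug upstream.
#'
#' @param x Numeric vector with values in `[-1, 1]`.
#' @return A list of class `"polar_repr"` with elements `phi` and `r`.
#' @export
#' @examples
#' to_polar(c(-1, 0, 1))$phi  # pi, pi/2, 0
to_polar <- function(x) {
  stopifnot(is.numeric(x))
  x <- as.double(x)
  if (any(abs(x) > 1 + 1e-9)) {
    abort("values outside [-1, 1]: normalize before the angular encoding",
          class = "etongue_domain_error")
  }
  x <- pmin(1, pmax(-1, x))
  structure(list(phi = acos(x), r = seq_along(x) / length(x)),
            class = "polar_repr")
}

#' Gramian Angular (Summation) Field of a signal
#'
#' Encodes a normalized series as the matrix `G_ij = cos(phi_i + phi_j)`
#' with `phi = arccos(x)` — equivalently
#' `x_i x_j - sqrt(1 - x_i^2) sqrt(1 - x_j^2)`. The Gram structure preserves
#' the temporal self-correlation of the series as image texture, which is
#' what makes the rendered matrix a visually discernible fingerprint of the
#' measurement. G is symmetric, bounded in `[-1, 1]`, with diagonal
#' `2 x_i^2 - 1`.
#'
#' @param x A numeric vector in `[-1, 1]` or a `"polar_repr"`.
#' @return An M-by-M matrix of class `"gaf_image"` with attribute
#'   `variant = "GAF"`.
#' @export
#' @examples
#' gaf(c(-1, 0, 1))
gaf <- function(x) {
  p <- if (inherits(x, "polar_repr")) x else to_polar(x)
  g <- cos(outer(p$phi, p$phi, "+"))
  structure(g, class = c("gaf_image", "matrix", "array"),
            variant = "GAF", weights = NULL)
}

#' Intensity-weighted Gramian field (GAF*)
#'
#' Per-measurement min-max normalization erases the absolute signal
#' amplitude before the angular encoding. GAF* re-injects it by scaling each
#' column j of the Gram matrix by a weight derived from the raw (unscaled)
#' signal: `G*_ij = G_ij * w_j`. By default the raw signal is min-max mapped
#' to `[0, 1]` first so the image stays within the renderable range; set
#' `scale_weights = FALSE` to weight by raw volts directly. A constant raw
#' signal yields unit weights (G unchanged).
#'
#' @param g A `"gaf_image"` of size M x M.
#' @param raw Numeric vector of length M: the PAA-reduced raw signal.
#' @param scale_weights Map `raw` to `[0, 1]` before weighting (default).
#' @return An M-by-M `"gaf_image"` with `variant = "GAF*"` and the weight
#'   vector stored in attribute `weights`.
#' @export
gaf_star <- function(g, raw, scale_weights = TRUE) {
  stopifnot(inherits(g, "gaf_image"))
  m <- nrow(g)
  raw <- as.double(raw)
  if (length(raw) != m) {
    stop_invalid(sprintf("`raw` has length %d but G is %d x %d", length(raw), m, m))
  }
  w <- if (scale_weights) {
    rng <- range(raw)
    if (rng[2] <= rng[1]) rep(1, m) else (raw - rng[1]) / (rng[2] - rng[1])
  } else {
    raw
  }
  out <- sweep(unclass(g), 2L, w, "*")
  structure(out, class = c("gaf_image", "matrix", "array"),
            variant = "GAF*", weights = w)
}

# small fixed perceptually-uniform lookup table (256 RGB rows, 0..255)
viridis_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      cols <- viridisLite::viridis(256)
      lut <<- round(grDevices::col2rgb(cols))  # 3 x 256
    }
    lut
  }
})

#' Render a Gramian matrix as an 8-bit image
#'
#' Affinely maps the matrix range `[min, max]` onto pixel values 0–255
#' (round-half-to-even; a constant matrix renders as all zeros) and expands
#' to three channels, either by replicating the gray plane or through a
#' fixed perceptually-uniform colormap. The matrix side must already equal
#' the requested resolution: resolution is set upstream by PAA on the
#' series, never by resampling the image, so the Gram structure is
#' preserved.
#'
#' @param g A `"gaf_image"` (or plain matrix), M x M.
#' @param resolution Expected side length; defaults to M.
#' @param channel_mode `"replicate"` or `"colormap"`.
#' @return An M x M x 3 integer array of class `"rendered_image"` with
#'   values in 0..255.
#' @export
render_image <- function(g, resolution = NULL,
                         channel_mode = c("replicate", "colormap")) {
  channel_mode <- match.arg(channel_mode)
  m <- unclass(g)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!is.null(resolution) && nrow(m) != resolution) {
    stop_invalid(sprintf("matrix is %d x %d but resolution %d was requested; choose the PAA length upstream",
                         nrow(m), ncol(m), resolution))
  }
  rng <- range(m)
  gray <- if (rng[2] > rng[1]) {
    round(255 * (m - rng[1]) / (rng[2] - rng[1]))
  } else {
    matrix(0, nrow(m), ncol(m))
  }
  px <- if (channel_mode == "replicate") {
    array(gray, dim = c(nrow(m), ncol(m), 3))
  } else {
    lut <- viridis_lut()
    array(c(lut[1, gray + 1], lut[2, gray + 1], lut[3, gray + 1]),
          dim = c(nrow(m), ncol(m), 3))
  }
  structure(px, class = "rendered_image",
            resolution = nrow(m), channel_mode = channel_mode)
}

#' Encode every recording of a dataset as a fingerprint image
#'
#' The full signal-to-image path, per measurement: extract the test window,
#' optionally baseline-correct, concatenate channels, PAA-reduce the
#' 1-D series to the working resolution, min-max normalize to `[-1, 1]`,
#' form the Gramian field (optionally intensity-weighted), and render to an
#' 8-bit image.
#'
#' @param data A tibble with a `recording` list column (from
#'   [simulate_task_data()] or [read_recordings()]).
#' @param variant `"gaf"` or `"gaf_star"`.
#' @param resolution Working image side length (PAA target), e.g. 96 or 224.
#' @param baseline Baseline correction mode, see [baseline_subtract()].
#' @param channel_mode Rendering mode, see [render_image()].
#' @param scale_weights For GAF*, map raw weights to `[0, 1]` (default).
#' @return The input tibble with an added `image` list column of
#'   `rendered_image` objects.
#' @export
#' @examples
#' d <- simulate_task_data("custom", sim_config(n_classes = 2, n_replicates = 2))
#' d <- encode_fingerprints(d, resolution = 48)
#' dim(d$image[[1]])
encode_fingerprints <- function(data, variant = c("gaf", "gaf_star"),
                                resolution = 96, baseline = "none",
                                channel_mode = "replicate",
                                scale_weights = TRUE) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(data), "recording" %in% names(data))
  images <- purrr::map(data$recording, function(rec) {
    raw <- signal_vector(rec, baseline = baseline)
    reduced <- paa_reduce(raw, resolution)
    g <- gaf(minmax_normalize(reduced))
    if (variant == "gaf_star") {
      g <- gaf_star(g, reduced, scale_weights = scale_weights)
    }
    render_image(g, resolution = resolution, channel_mode = channel_mode)
  })
  dplyr::mutate(data, image = images)
}

#' Plot a Gramian fingerprint
#'
#' @param x A `"gaf_image"` or `"rendered_image"`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(x, title = NULL) {
  m <- if (inherits(x, "rendered_image")) x[, , 1] else unclass(x)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
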