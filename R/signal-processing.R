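#' Extract the test-phase window of a recording
#'
#' Returns the final `test_duration_s * sample_rate_hz` samples of every
#' channel — the portion recorded while the array is immersed in the test
#' liquid. Only this window enters the fingerprint; the reference dwell and
#' any rinse are discarded.
#'
#' @param rec A `sensor_recording`.
#' @return A channels-by-T numeric matrix of voltages.
#' @export
#' @examples
#' rec <- simulate_recording(rep(0.05, 15), sim_config(), replicate_seed = 1)
#' dim(extract_test_window(rec))  # 15 x 60
extract_test_window <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  n_total <- ncol(rec$voltages)
  n_declared <- round((rec$ref_duration_s + rec$test_duration_s) * rec$sample_rate_hz)
  if (n_declared > n_total) {
    abort(sprintf(
      "recording has %d samples but declared phases need %d", n_total, n_declared
    ), class = "etongue_length_error")
  }
  n_test <- round(rec$test_duration_s * rec$sample_rate_hz)
  rec$voltages[, (n_total - n_test + 1L):n_total, drop = FALSE]
}

#' Baseline-correct a test window against the reference phase
#'
#' With `mode = "last_ref_mean"` each channel's mean over the final 10 s of
#' the reference dwell is subtracted from its test-phase samples, so every
#' channel starts near zero. The default `mode = "none"` leaves the window
#' untouched: the raw test-phase voltages are what gets encoded.
#'
#' @param window A channels-by-T matrix from [extract_test_window()].
#' @param rec The `sensor_recording` the window came from (needed for the
#'   reference phase).
#' @param mode `"none"` (identity) or `"last_ref_mean"`.
#' @return A matrix of the same shape.
#' @export
baseline_subtract <- function(window, rec, mode = c("none", "last_ref_mean")) {
  mode <- match.arg(mode)
  if (mode == "none") return(window)
  stopifnot(inherits(rec, "sensor_recording"))
  n_ref <- round(rec$ref_duration_s * rec$sample_rate_hz)
  if (n_ref < 1) stop_invalid("last_ref_mean requires a reference phase")
  n_tail <- min(n_ref, round(10 * rec$sample_rate_hz))
  ref_tail <- rec$voltages[, (n_ref - n_tail + 1L):n_ref, drop = FALSE]
  sweep(window, 1L, rowMeans(ref_tail), "-")
}

#' Concatenate channels into a spectrum-like vector
#'
#' Joins the per-channel test-phase traces end to end, channel-major: all of
#' channel 1's samples, then channel 2's, and so on. At the defaults
#' (15 channels, 60 s at 1 Hz) this yields a 900-point vector. The Gramian
#' encoding depends on this ordering, so it is deterministic and explicit.
#'
#' @param window A channels-by-T matrix.
#' @param order Optional permutation of channel indices or rownames giving
#'   the concatenation order; defaults to ascending channel index.
#' @return A numeric vector of length `channels * T` with attribute
#'   `channel_order`.
#' @export
#' @examples
#' concatenate_channels(matrix(1:6, nrow = 2, byrow = TRUE))  # 1 2 3 4 5 6
concatenate_channels <- function(window, order = NULL) {
  stopifnot(is.matrix(window))
  n_ch <- nrow(window)
  if (is.null(order)) order <- seq_len(n_ch)
  if (is.character(order)) {
    order <- match(order, rownames(window))
    if (anyNA(order)) stop_invalid("`order` names not found among channels")
  }
  if (length(order) != n_ch || !setequal(order, seq_len(n_ch))) {
    stop_invalid("`order` must be a permutation of the channels")
  }
  values <- as.vector(t(window[order, , drop = FALSE]))
  ch_names <- rownames(window) %||% sprintf("ch%02d", seq_len(n_ch))
  attr(values, "channel_order") <- ch_names[order]
  values
}

#' Min-max normalize a signal to [-1, 1]
#'
#' Affinely maps the per-measurement range `[min, max]` onto `[-1, 1]`, the
#' domain the angular encoding requires. A constant signal (zero range) maps
#' to all zeros rather than erroring, so degenerate fixtures flow through.
#' Alternatively, fixed dataset-level bounds may be supplied to normalize
#' every measurement on a common scale.
#'
#' @param x Numeric vector.
#' @param scale_min,scale_max Optional fixed bounds; default to `range(x)`.
#' @return A numeric vector in `[-1, 1]` with attributes `scale_min` and
#'   `scale_max` recording the bounds used.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))  # -1 0 1
minmax_normalize <- function(x, scale_min = NULL, scale_max = NULL) {
  stopifnot(is.numeric(x))
  x <- as.double(x)
  lo <- scale_min %||% min(x)
  hi <- scale_max %||% max(x)
  if (hi <= lo) {
    out <- rep(0, length(x))
  } else {
    out <- 2 * (x - lo) / (hi - lo) - 1
    out <- pmin(1, pmax(-1, out))
  }
  attr(out, "scale_min") <- lo
  attr(out, "scale_max") <- hi
  out
}

#' Piecewise aggregate approximation (PAA)
#'
#' Downsamples a series of length N to M segment means, with segment m
#' covering indices `(floor((m-1) N / M), floor(m N / M)]`. Used to bring the
#' 900-point concatenated signal down to the working resolution of the image
#' encoder (e.g. 96 or 224) before the Gram matrix is formed, keeping the
#' encoding cost quadratic in M rather than N. `target_length == N` is the
#' identity.
#'
#' @param x Numeric vector.
#' @param target_length Output length M, `1 <= M <= length(x)`.
#' @return Numeric vector of length `target_length`.
#' @export
#' @examples
#' paa_reduce(c(1, 2, 3, 4), 2)  # 1.5 3.5
paa_reduce <- function(x, target_length) {
  stopifnot(is.numeric(x))
  n <- length(x)
  m <- check_count(target_length, "target_length")
  if (m > n) stop_invalid("`target_length` must not exceed length(x)")
  if (m == n) return(as.double(x))
  starts <- floor((seq_len(m) - 1) * n / m) + 1L
  ends <- floor(seq_len(m) * n / m)
  vapply(seq_len(m), function(i) mean(x[starts[i]:ends[i]]), numeric(1))
}

# test window -> concatenated (optionally baseline-corrected) raw vector
signal_vector <- function(rec, baseline = "none", order = NULL) {
  window <- extract_test_window(rec)
  window <- baseline_subtract(window, rec, mode = baseline)
  concatenate_channels(window, order = order)
}
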