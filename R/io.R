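#' Write a dataset of recordings as delimited text
#'
#' One CSV per measurement (`t_s,ch01,...` header, one row per sample) plus
#' a `manifest.csv` with columns `file,label,product_id,phase_split_s`.
#'
#' @param data A tibble with `sample_id`, `label`, `product_id` and a
#'   `recording` list column.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_recordings <- function(data, dir) {
  stopifnot(is.data.frame(data), "recording" %in% names(data))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    rec <- data$recording[[i]]
    df <- as.data.frame(t(rec$voltages))
    names(df) <- rownames(rec$voltages) %||% sprintf("ch%02d", seq_len(nrow(rec$voltages)))
    df <- cbind(t_s = seq_len(ncol(rec$voltages)) / rec$sample_rate_hz, df)
    files[i] <- paste0(data$sample_id[i], ".csv")
    readr::write_csv(df, file.path(dir, files[i]))
  }
  manifest <- tibble(
    file = files, label = data$label,
    product_id = data$product_id %||% NA_character_,
    phase_split_s = vapply(data$recording, function(r) r$ref_duration_s, numeric(1))
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read one recording from delimited text
#'
#' Parses the CSV dialect written by [write_recordings()] (`t_s` column
#' followed by one column per channel; CRLF endings and `#` comment lines
#' tolerated) and attaches phase annotations from the manifest entry.
#'
#' @param path Path to the recording CSV.
#' @param manifest_entry A one-row data frame (or list) with at least
#'   `phase_split_s` and optionally `label`, `product_id`.
#' @param sample_rate_hz Sampling rate (default 1 Hz).
#' @param n_channels Expected channel count; mismatch raises a schema
#'   error.
#' @return A `sensor_recording`.
#' @export
read_recording <- function(path, manifest_entry, sample_rate_hz = 1,
                           n_channels = NULL) {
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path,
                                      conditionMessage(e)),
                              class = "etongue_parse_error")
  )
  if (!"t_s" %in% names(df) || ncol(df) < 2) {
    abort(sprintf("'%s': expected a t_s column plus channel columns", path),
          class = "etongue_schema_error")
  }
  if (anyNA(df)) {
    abort(sprintf("'%s': missing values in recording", path),
          class = "etongue_parse_error")
  }
  v <- t(as.matrix(df[, setdiff(names(df), "t_s"), drop = FALSE]))
  if (!is.null(n_channels) && nrow(v) != n_channels) {
    abort(sprintf("'%s': %d channels found, %d expected", path, nrow(v), n_channels),
          class = "etongue_schema_error")
  }
  split_s <- as.double(manifest_entry$phase_split_s)
  n_total <- ncol(v)
  new_sensor_recording(
    v, sample_rate_hz,
    ref_duration_s = split_s,
    test_duration_s = n_total / sample_rate_hz - split_s,
    label = as.character(manifest_entry$label %||% NA_character_),
    product_id = as.character(manifest_entry$product_id %||% NA_character_)
  )
}

#' Read a dataset written by [write_recordings()]
#'
#' @param dir Directory holding the recording CSVs and `manifest.csv`.
#' @param sample_rate_hz Sampling rate (default 1 Hz).
#' @return A tibble with `sample_id`, `label`, `product_id`, `recording`.
#' @export
read_recordings <- function(dir, sample_rate_hz = 1) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"), comment = "#",
                              show_col_types = FALSE, progress = FALSE)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, manifest$file[i]), manifest[i, ],
                   sample_rate_hz = sample_rate_hz)
  })
  n_ch <- vapply(recs, function(r) nrow(r$voltages), integer(1))
  if (length(unique(n_ch)) > 1) {
    abort("channel count differs across recordings", class = "etongue_schema_error")
  }
  tibble(
    sample_id = sub("\\.csv$", "", manifest$file),
    label = as.character(manifest$label),
    product_id = as.character(manifest$product_id),
    recording = recs
  )
}

#' Write a rendered fingerprint as a PNG file
#'
#' @param img A `"rendered_image"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fingerprint_png <- function(img, path) {
  stopifnot(inherits(img, "rendered_image"))
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' Persist embeddings as delimited text
#'
#' Writes the n x d embedding matrix as CSV preceded by `#` header lines
#' naming the extractor, the dimension and a content hash, so persisted
#' features are self-describing and verifiable.
#'
#' @param data Featurized tibble (columns `sample_id`, `label`,
#'   `embedding`).
#' @param path Output file.
#' @param extractor_name Name recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(data, path, extractor_name = "builtin") {
  m <- embedding_matrix(data)
  hash <- rlang::hash(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# extractor: %s", extractor_name),
    sprintf("# dim: %d", ncol(m)),
    sprintf("# hash: %s", hash)
  ), con)
  df <- data.frame(sample_id = data$sample_id, label = data$label, m,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `"et_eval"` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "et_eval"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_capability("jsonlite is required to write JSON reports")
  }
  jsonlite::write_json(
    list(
      protocol = report$protocol, head = report$head,
      n_components = report$n_components,
      mean_accuracy = report$mean_accuracy, sd_accuracy = report$sd_accuracy,
      n_correct = report$n_correct, n_test_total = report$n_test_total,
      per_rep = report$per_rep,
      confusion = as.data.frame(report$confusion)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
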