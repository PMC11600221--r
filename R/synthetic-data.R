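#' Simulation settings for the synthetic sensor array
#'
#' Bundles every knob of the synthetic potentiometric simulator. The defaults
#' emulate a 15-electrode differential array sampled at 1 Hz: a 100 s dwell in
#' the reference liquid followed by a 60 s test-liquid immersion during which
#' each channel relaxes exponentially towards a class-specific steady-state
#' voltage shift.
#'
#' @param n_classes Number of sample classes (used by the `"custom"` task
#'   layout; the named task layouts fix their own class counts).
#' @param n_replicates Measurement replicates per class (or per product for
#'   product-structured layouts).
#' @param n_channels Number of differential voltage channels.
#' @param ref_duration_s Reference-phase dwell time in seconds.
#' @param test_duration_s Test-phase immersion time in seconds.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param separation Dimensionless scale of the between-class archetype
#'   distance; `0` collapses all classes onto one archetype.
#' @param noise_sd Standard deviation of the per-sample Gaussian voltage
#'   noise, in volts.
#' @param replicate_sd Standard deviation of the replicate-to-replicate jitter
#'   applied to the steady-state shift vector, in volts.
#' @param drift_rate Slow linear baseline drift, in volts per second.
#' @param tau_s Time constant of the exponential approach to steady state,
#'   in seconds.
#' @param baseline_sd Standard deviation of the static per-channel baseline
#'   offsets, in volts.
#' @param archetype_scale Voltage scale of the class steady-state shifts at
#'   `separation = 1`, in volts.
#' @param product_offset_frac Within-class product offsets as a fraction of
#'   the between-class archetype scale (product-structured layouts only).
#' @param seed Root seed; all randomness in a dataset derives from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_channels
sim_config <- function(n_classes = 7, n_replicates = 10, n_channels = 15,
                       ref_duration_s = 100, test_duration_s = 60,
                       sample_rate_hz = 1, separation = 1,
                       noise_sd = 0.002, replicate_sd = 0.005,
                       drift_rate = 1e-5, tau_s = 10, baseline_sd = 0.05,
                       archetype_scale = 0.05, product_offset_frac = 0.4,
                       seed = 1) {
  cfg <- list(
    n_classes = check_count(n_classes, "n_classes"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    n_channels = check_count(n_channels, "n_channels"),
    ref_duration_s = check_count(ref_duration_s, "ref_duration_s"),
    test_duration_s = check_count(test_duration_s, "test_duration_s"),
    sample_rate_hz = check_scalar(sample_rate_hz, "sample_rate_hz", 0, strict = TRUE),
    separation = check_scalar(separation, "separation", 0),
    noise_sd = check_scalar(noise_sd, "noise_sd", 0),
    replicate_sd = check_scalar(replicate_sd, "replicate_sd", 0),
    drift_rate = check_scalar(drift_rate, "drift_rate"),
    tau_s = check_scalar(tau_s, "tau_s", 0, strict = TRUE),
    baseline_sd = check_scalar(baseline_sd, "baseline_sd", 0),
    archetype_scale = check_scalar(archetype_scale, "archetype_scale", 0),
    product_offset_frac = check_scalar(product_offset_frac, "product_offset_frac", 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "sim_config")
}

#' Draw per-class steady-state response archetypes
#'
#' Each class of liquid perturbs the sensor array towards its own vector of
#' steady-state voltage shifts. Archetype shift vectors are drawn i.i.d.
#' Gaussian and scaled by `separation`, so the expected pairwise distance
#' between class archetypes grows linearly with `separation` and collapses to
#' zero (identical archetypes) at `separation = 0`.
#'
#' @param n_classes Number of classes.
#' @param n_channels Number of sensor channels.
#' @param separation Dimensionless between-class distance scale.
#' @param seed Integer seed.
#' @param archetype_scale Voltage scale at `separation = 1` (volts).
#' @param class_labels Optional character vector of class names.
#'
#' @return A tibble with columns `class_label` and `delta_v` (list column of
#'   per-channel steady-state shifts, volts).
#' @export
#' @examples
#' make_class_archetypes(3, 15, separation = 1, seed = 1)
make_class_archetypes <- function(n_classes, n_channels, separation, seed,
                                  archetype_scale = 0.05,
                                  class_labels = NULL) {
  n_classes <- check_count(n_classes, "n_classes")
  n_channels <- check_count(n_channels, "n_channels")
  separation <- check_scalar(separation, "separation", 0)
  if (is.null(class_labels)) {
    class_labels <- sprintf("class_%d", seq_len(n_classes))
  }
  stopifnot(length(class_labels) == n_classes)
  deltas <- with_seed(seed, {
    lapply(seq_len(n_classes), function(i) {
      separation * archetype_scale * rnorm(n_channels)
    })
  })
  tibble(class_label = class_labels, delta_v = deltas)
}

new_sensor_recording <- function(voltages, sample_rate_hz, ref_duration_s,
                                 test_duration_s, label = NA_character_,
                                 product_id = NA_character_) {
  structure(
    list(
      voltages = voltages,
      sample_rate_hz = sample_rate_hz,
      ref_duration_s = ref_duration_s,
      test_duration_s = test_duration_s,
      label = label,
      product_id = product_id
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %d channels x %d samples (%g s ref + %g s test @ %g Hz)%s\n",
    nrow(x$voltages), ncol(x$voltages), x$ref_duration_s, x$test_duration_s,
    x$sample_rate_hz,
    if (is.na(x$label)) "" else paste0(" label=", x$label)
  ))
  invisible(x)
}

#' Simulate a single multichannel recording
#'
#' Generates one measurement of the model sensor array: during the reference
#' phase every channel fluctuates around its static baseline; once the array
#' enters the test liquid each channel relaxes exponentially (time constant
#' `tau_s`) towards `baseline + delta_v`, on top of a slow linear drift and
#' i.i.d. Gaussian noise. Replicate-to-replicate variability perturbs the
#' steady-state shift vector itself.
#'
#' @param delta_v Per-channel steady-state voltage shifts (volts); one row of
#'   [make_class_archetypes()] output.
#' @param config A [sim_config()].
#' @param replicate_seed Integer seed for this replicate's noise draws.
#' @param label,product_id Optional identifiers carried on the recording.
#'
#' @return A `sensor_recording`: a channels-by-time voltage matrix plus phase
#'   annotations.
#' @export
#' @examples
#' arch <- make_class_archetypes(1, 15, 1, seed = 1)
#' rec <- simulate_recording(arch$delta_v[[1]], sim_config(), replicate_seed = 5)
#' dim(rec$voltages)
simulate_recording <- function(delta_v, config, replicate_seed,
                               label = NA_character_,
                               product_id = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  if (length(delta_v) != config$n_channels) {
    stop_invalid("`delta_v` length must equal `config$n_channels`.")
  }
  n_ref <- as.integer(round(config$ref_duration_s * config$sample_rate_hz))
  n_test <- as.integer(round(config$test_duration_s * config$sample_rate_hz))
  n_ch <- config$n_channels
  dt <- 1 / config$sample_rate_hz

  # static per-channel electrode offsets, shared across the whole dataset
  baseline <- with_seed(derive_seed(config$seed, 0L), {
    rnorm(n_ch, sd = config$baseline_sd)
  })

  with_seed(replicate_seed, {
    delta_eff <- delta_v + rnorm(n_ch, sd = config$replicate_sd)
    t_all <- seq_len(n_ref + n_test) * dt
    v <- matrix(0, nrow = n_ch, ncol = n_ref + n_test)
    for (c in seq_len(n_ch)) {
      resp <- numeric(n_ref + n_test)
      if (n_test > 0) {
        t_test <- seq_len(n_test) * dt
        resp[n_ref + seq_len(n_test)] <- delta_eff[c] * (1 - exp(-t_test / config$tau_s))
      }
      v[c, ] <- baseline[c] + config$drift_rate * t_all + resp +
        rnorm(n_ref + n_test, sd = config$noise_sd)
    }
    rownames(v) <- sprintf("ch%02d", seq_len(n_ch))
    new_sensor_recording(v, config$sample_rate_hz, config$ref_duration_s,
                         config$test_duration_s, label, product_id)
  })
}

# layout tables for the named tasks --------------------------------------

task_layout <- function(task, config) {
  switch(task,
    wine = list(
      classes = sprintf("wine_%d", 1:7),
      reps = 10
    ),
    protein = list(
      classes = sprintf("protein_%d", 1:6),
      reps = 10
    ),
    custom = list(
      classes = sprintf("class_%d", seq_len(config$n_classes)),
      reps = config$n_replicates
    ),
    stop_invalid(sprintf("unknown task layout '%s'", task))
  )
}

simulate_flat_task <- function(classes, reps, config) {
  arch <- make_class_archetypes(length(classes), config$n_channels,
                                config$separation, derive_seed(config$seed, 1L),
                                archetype_scale = config$archetype_scale,
                                class_labels = classes)
  rows <- list()
  for (i in seq_along(classes)) {
    for (r in seq_len(reps)) {
      rec <- simulate_recording(
        arch$delta_v[[i]], config,
        replicate_seed = derive_seed(config$seed, i, r),
        label = classes[i]
      )
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sprintf("%s_r%02d", classes[i], r),
        label = classes[i],
        product_id = NA_character_,
        recording = list(rec)
      )
    }
  }
  dplyr::bind_rows(rows)
}

simulate_sugar_task <- function(config) {
  sugars <- c("glucose", "sucrose")
  levels_pct <- c(2.5, 5, 10)
  # concentration embeds as a scaling of the sugar's steady-state shift,
  # preserving the 2.5 : 5 : 10 ratio so mid-level relabeling is meaningful
  arch <- make_class_archetypes(2, config$n_channels, config$separation,
                                derive_seed(config$seed, 1L),
                                archetype_scale = config$archetype_scale,
                                class_labels = sugars)
  rows <- list()
  for (i in seq_along(sugars)) {
    for (j in seq_along(levels_pct)) {
      scale <- levels_pct[j] / max(levels_pct)
      lab <- sprintf("%s_%g", sugars[i], levels_pct[j])
      for (r in seq_len(config$n_replicates)) {
        rec <- simulate_recording(
          scale * arch$delta_v[[i]], config,
          replicate_seed = derive_seed(config$seed, i, j, r),
          label = lab
        )
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = sprintf("%s_r%02d", lab, r),
          label = lab, product_id = NA_character_,
          sugar = sugars[i], level_pct = levels_pct[j],
          recording = list(rec)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

simulate_product_task <- function(class_products, reps, config) {
  classes <- names(class_products)
  arch <- make_class_archetypes(length(classes), config$n_channels,
                                config$separation, derive_seed(config$seed, 1L),
                                archetype_scale = config$archetype_scale,
                                class_labels = classes)
  offset_sd <- config$product_offset_frac * config$separation * config$archetype_scale
  rows <- list()
  for (i in seq_along(classes)) {
    n_prod <- class_products[[i]]
    offsets <- with_seed(derive_seed(config$seed, 2L, i), {
      lapply(seq_len(n_prod), function(p) rnorm(config$n_channels, sd = offset_sd))
    })
    for (p in seq_len(n_prod)) {
      pid <- sprintf("%s_p%d", classes[i], p)
      for (r in seq_len(reps)) {
        rec <- simulate_recording(
          arch$delta_v[[i]] + offsets[[p]], config,
          replicate_seed = derive_seed(config$seed, i, p, r),
          label = classes[i], product_id = pid
        )
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = sprintf("%s_r%02d", pid, r),
          label = classes[i], product_id = pid,
          recording = list(rec)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a labeled synthetic dataset for a benchmark task layout
#'
#' Produces a full synthetic dataset following one of the study layouts:
#' \describe{
#'   \item{`"wine"`}{7 wines x 10 replicates = 70 measurements.}
#'   \item{`"protein"`}{6 protein products x 10 replicates = 60 measurements.}
#'   \item{`"sugar"`}{2 sugar types x 3 concentration levels (2.5/5/10 % w/w)
#'     x 10 replicates = 60 measurements; concentration scales the shift
#'     vector so level ordering is embedded in the signal.}
#'   \item{`"milk"`}{12 commercial products mapped to 5 protein-source
#'     classes (almond 2, cow 2, soy 2, oat 3, pea 3 products), 5 replicates
#'     each = 60 measurements; products within a class share the class
#'     archetype plus a smaller per-product offset.}
#'   \item{`"clustering"`}{4 beverage categories (coffee 8, juice 9,
#'     water 8, wine 7 products), 5 replicates each = 160 measurements.}
#'   \item{`"custom"`}{`config$n_classes` x `config$n_replicates`.}
#' }
#'
#' @param task One of `"wine"`, `"protein"`, `"sugar"`, `"milk"`,
#'   `"clustering"`, `"custom"`.
#' @param config A [sim_config()].
#' @param milk_roster Named integer vector giving products per source class
#'   for the milk layout.
#'
#' @return A tibble with one row per measurement: `sample_id`, `label`,
#'   `product_id` and a `recording` list column of `sensor_recording`
#'   objects (plus `sugar`/`level_pct` for the sugar layout).
#' @export
#' @examples
#' wine <- simulate_task_data("wine", sim_config(seed = 1))
#' nrow(wine)
simulate_task_data <- function(task = c("wine", "protein", "sugar", "milk",
                                        "clustering", "custom"),
                               config = sim_config(),
                               milk_roster = c(almond = 2, cow = 2, soy = 2,
                                               oat = 3, pea = 3)) {
  if (!is.character(task) || length(task) != 1L ||
      !task %in% c("wine", "protein", "sugar", "milk", "clustering", "custom")) {
    stop_invalid("unknown task; use wine, protein, sugar, milk, clustering or custom")
  }
  stopifnot(inherits(config, "sim_config"))
  switch(task,
    sugar = simulate_sugar_task(config),
    milk = {
      if (is.null(names(milk_roster)) || any(milk_roster < 1)) {
        stop_invalid("`milk_roster` must be a named vector of positive counts")
      }
      simulate_product_task(as.list(milk_roster), reps = 5, config = config)
    },
    clustering = simulate_product_task(
      list(coffee = 8, juice = 9, water = 8, wine = 7),
      reps = 5, config = config
    ),
    {
      lay <- task_layout(task, config)
      simulate_flat_task(lay$classes, lay$reps, config)
    }
  )
}
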