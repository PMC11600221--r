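test_that("archetypes have the right shape and respond to separation", {
  a <- make_class_archetypes(7, 15, 1.0, seed = 1)
  expect_equal(nrow(a), 7)
  expect_true(all(vapply(a$delta_v, length, integer(1)) == 15))

  # zero separation collapses every class onto one archetype
  a0 <- make_class_archetypes(3, 15, 0.0, seed = 1)
  expect_equal(a0$delta_v[[1]], a0$delta_v[[2]])
  expect_equal(a0$delta_v[[2]], a0$delta_v[[3]])

  # mean pairwise distance grows with separation (computed directly)
  pairdist <- function(arch) {
    d <- do.call(rbind, arch$delta_v)
    mean(dist(d))
  }
  hi <- pairdist(make_class_archetypes(5, 15, 2.0, seed = 1))
  lo <- pairdist(make_class_archetypes(5, 15, 0.5, seed = 1))
  expect_gt(hi, lo)
  expect_equal(hi / lo, 4, tolerance = 1e-10)  # linear scaling

  expect_error(make_class_archetypes(0, 15, 1, seed = 1),
               class = "etongue_invalid_argument")
  expect_error(make_class_archetypes(3, 15, -1, seed = 1),
               class = "etongue_invalid_argument")
})

test_that("simulated recordings follow the response model", {
  cfg <- sim_config(seed = 1)
  arch <- make_class_archetypes(1, 15, 1, seed = 2)
  rec <- simulate_recording(arch$delta_v[[1]], cfg, replicate_seed = 7)
  expect_s3_class(rec, "sensor_recording")
  expect_equal(dim(rec$voltages), c(15, 160))  # 100 s + 60 s at 1 Hz

  # noiseless limit: test phase converges to baseline + delta_v per channel
  cfg0 <- sim_config(noise_sd = 0, replicate_sd = 0, drift_rate = 0,
                     tau_s = 5, seed = 1)
  rec0 <- simulate_recording(arch$delta_v[[1]], cfg0, replicate_seed = 7)
  baseline <- rec0$voltages[, 100]          # end of reference phase
  final <- rec0$voltages[, 160]             # end of test phase (12 tau)
  expect_equal(final - baseline, arch$delta_v[[1]], tolerance = 1e-4,
               ignore_attr = TRUE)

  # determinism: identical seeds reproduce the recording bit-for-bit
  rec2 <- simulate_recording(arch$delta_v[[1]], cfg, replicate_seed = 7)
  expect_identical(rec$voltages, rec2$voltages)
})

test_that("task layouts match the study designs", {
  cfg <- sim_config(n_channels = 4, ref_duration_s = 10, test_duration_s = 8,
                    seed = 1)
  wine <- simulate_task_data("wine", cfg)
  expect_equal(nrow(wine), 70)
  expect_equal(length(unique(wine$label)), 7)
  expect_true(all(table(wine$label) == 10))

  protein <- simulate_task_data("protein", cfg)
  expect_equal(nrow(protein), 60)
  expect_equal(length(unique(protein$label)), 6)

  sugar <- simulate_task_data("sugar", cfg)
  expect_equal(nrow(sugar), 60)
  expect_setequal(unique(sugar$sugar), c("glucose", "sucrose"))
  expect_setequal(unique(sugar$level_pct), c(2.5, 5, 10))
  expect_true(all(table(sugar$sugar, sugar$level_pct) == 10))

  milk <- simulate_task_data("milk", cfg)
  expect_equal(nrow(milk), 60)
  expect_equal(length(unique(milk$product_id)), 12)
  expect_equal(length(unique(milk$label)), 5)
  expect_true(all(table(milk$product_id) == 5))
  # every source class has at least two products
  roster <- table(unique(milk[, c("product_id", "label")])$label)
  expect_true(all(roster >= 2))

  clust <- simulate_task_data("clustering", cfg)
  expect_equal(nrow(clust), 160)
  expect_equal(length(unique(clust$label)), 4)
  expect_equal(length(unique(clust$product_id)), 32)

  expect_error(simulate_task_data("beer", cfg),
               class = "etongue_invalid_argument")
})

test_that("sugar concentration scales the steady-state shift in ratio 2.5:5:10", {
  cfg <- sim_config(n_channels = 4, ref_duration_s = 10, test_duration_s = 40,
                    noise_sd = 0, replicate_sd = 0, drift_rate = 0, tau_s = 2,
                    seed = 3)
  sugar <- simulate_task_data("sugar", cfg)
  shift_of <- function(lab) {
    rec <- sugar$recording[[match(lab, sugar$label)]]
    rec$voltages[, ncol(rec$voltages)] - rec$voltages[, 10]
  }
  lo <- shift_of("glucose_2.5"); mid <- shift_of("glucose_5"); hi <- shift_of("glucose_10")
  expect_equal(mid / lo, rep(2, 4), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(hi / lo, rep(4, 4), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("identical config and seed reproduce a whole dataset", {
  cfg <- tiny_config(seed = 11)
  d1 <- simulate_task_data("custom", cfg)
  d2 <- simulate_task_data("custom", cfg)
  expect_identical(
    lapply(d1$recording, `[[`, "voltages"),
    lapply(d2$recording, `[[`, "voltages")
  )
  # a different seed changes the data
  d3 <- simulate_task_data("custom", tiny_config(seed = 12))
  expect_false(identical(d1$recording[[1]]$voltages, d3$recording[[1]]$voltages))
})

test_that("downstream accuracy grows with separation and is chance at zero", {
  accs <- sapply(c(0, 0.5, 2.0), function(sep) {
    mean(sapply(1:10, function(s) {
      d <- featurized_fixture("custom", seed = 100 + s, separation = sep,
                              noise_sd = 0.01, replicate_sd = 0.02)
      evaluate_kfold(d, head = "lda", n_components = 5, reps = 4,
                     seed = s)$mean_accuracy
    }))
  })
  expect_true(accs[2] >= accs[1])
  expect_true(accs[3] >= accs[2])
  # chance level for 3 classes is 1/3; binomial 95% interval over the pooled
  # predictions (10 seeds x 4 reps x 3 test samples = 120)
  p <- 1 / 3
  half <- 1.96 * sqrt(p * (1 - p) / 120)
  expect_lt(abs(accs[1] - p), half + 0.02)
})

test_that("recordings round-trip through the CSV dialect", {
  d <- simulate_task_data("custom", tiny_config(seed = 5))[1:4, ]
  dir <- withr::local_tempdir()
  write_recordings(d, dir)
  back <- read_recordings(dir)
  expect_equal(nrow(back), 4)
  expect_equal(back$label, d$label)
  for (i in 1:4) {
    expect_equal(back$recording[[i]]$voltages, d$recording[[i]]$voltages,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(back$recording[[i]]$ref_duration_s, 20)
    expect_equal(back$recording[[i]]$test_duration_s, 16)
  }
})
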