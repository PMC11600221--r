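two_blob_fixture <- function(n = 10, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, mean = sep), n, 2))
  list(x = x, y = rep(c("a", "b"), each = n))
}

test_that("head specifications pin the stated hyperparameters", {
  expect_equal(head_spec("rf")$hyperparameters$ntree, 50)
  expect_equal(head_spec("KNN")$hyperparameters$k, 3)
  expect_error(head_spec("mlp"), class = "etongue_invalid_argument")
})

test_that("every head trains, predicts known labels and is seed-deterministic", {
  fx <- two_blob_fixture()
  for (h in c("rf", "lda", "knn", "svm", "et", "xgb")) {
    fit <- train_head(h, fx$x, fx$y, seed = 42)
    pred <- predict_head(fit, fx$x)
    expect_true(all(pred %in% c("a", "b")), info = h)
    # linearly separated blobs: perfect training accuracy
    expect_equal(mean(pred == fx$y), 1, info = h)
    # identical seed, identical predictions
    fit2 <- train_head(h, fx$x, fx$y, seed = 42)
    expect_identical(pred, predict_head(fit2, fx$x), info = h)
  }
  expect_error(train_head("lda", fx$x, rep("a", 20)),
               class = "etongue_invalid_argument")
})

test_that("3-NN returns a training point's own label and matches class::knn", {
  fx <- two_blob_fixture(n = 8, sep = 6, seed = 2)
  fit <- train_head("knn", fx$x, fx$y)
  expect_equal(predict_head(fit, fx$x[3, , drop = FALSE]), fx$y[3])
  # cross-check the whole prediction against the reference implementation
  # on a tie-free query set
  set.seed(3)
  q <- rbind(matrix(rnorm(10, sd = 0.5), 5, 2),
             matrix(rnorm(10, mean = 6, sd = 0.5), 5, 2))
  expect_equal(predict_head(fit, q),
               as.character(class::knn(fx$x, q, fx$y, k = 3)))
})

test_that("repeated stratified resampling reports honest aggregates", {
  d <- featurized_fixture("custom", seed = 1)
  r <- evaluate_kfold(d, head = "lda", n_components = 5, reps = 8, seed = 3)
  expect_s3_class(r, "et_eval")
  expect_equal(nrow(r$per_rep), 8)
  # mean/std recomputable from the stored per-repetition vector
  expect_equal(r$mean_accuracy, mean(r$per_rep$accuracy), tolerance = 1e-12)
  expect_equal(r$sd_accuracy, sd(r$per_rep$accuracy), tolerance = 1e-12)
  # confusion row sums equal per-class test counts over all repetitions
  expect_true(all(rowSums(r$confusion) == 8 * 1))  # floor(6 * 0.2) = 1/class
  # identical seeds reproduce the report
  r2 <- evaluate_kfold(d, head = "lda", n_components = 5, reps = 8, seed = 3)
  expect_equal(r$per_rep$accuracy, r2$per_rep$accuracy)
  # tidy/glance accessors
  expect_equal(nrow(tidy(r)), 8)
  expect_equal(glance(r)$mean_accuracy, r$mean_accuracy)

  small <- d[c(1:4, 7:12, 13:18), ]  # one class with < 5 instances
  expect_error(evaluate_kfold(small, reps = 2),
               class = "etongue_protocol_error")
})

test_that("the random baseline sits at chance level", {
  d <- featurized_fixture("custom", seed = 2)  # 3 balanced classes
  r <- evaluate_kfold(d, head = "random", n_components = 2, reps = 50, seed = 1)
  p <- 1 / 3
  # three binomial standard errors around chance
  expect_lt(abs(r$mean_accuracy - p), 3 * sqrt(p * (1 - p) / r$n_test_total))
})

test_that("sugar leave-one-class-out pools 40 held-out predictions", {
  s <- simulate_task_data("sugar", tiny_config(seed = 3)) |>
    encode_fingerprints(resolution = 48) |>
    extract_features()
  r <- evaluate_sugar_locov(s, head = "lda", n_components = 5, seed = 1)
  # 4 held-out extreme cells x 6 replicates in the small fixture
  expect_equal(r$n_test_total, 24)
  expect_equal(nrow(r$per_rep), 4)         # one iteration per extreme cell
  expect_equal(r$mean_accuracy, r$n_correct / 24, tolerance = 1e-12)
  # pooled truth covers each extreme class exactly once
  expect_true(all(rowSums(r$confusion) == 6))
  # classes are the four type x level categories
  expect_setequal(rownames(r$confusion),
                  c("glucose_low", "glucose_high", "sucrose_low", "sucrose_high"))
  # missing level breaks the protocol
  expect_error(evaluate_sugar_locov(s[s$level_pct != 5, ]),
               class = "etongue_protocol_error")
})

test_that("milk leave-one-product-out holds products out, never classes", {
  m <- simulate_task_data("milk", tiny_config(seed = 4)) |>
    encode_fingerprints(resolution = 48) |>
    extract_features()
  r <- evaluate_milk_lopo(m, head = "lda", n_components = 5, seed = 1)
  expect_equal(nrow(r$per_rep), 12)        # one iteration per product
  expect_equal(r$n_test_total, 60)
  expect_equal(r$mean_accuracy, r$n_correct / 60, tolerance = 1e-12)

  # with near-homogeneous products a perfect classifier leaves a
  # diagonal-only confusion matrix
  easy <- simulate_task_data("milk", tiny_config(seed = 4,
                                                 product_offset_frac = 0.1)) |>
    encode_fingerprints(resolution = 48) |>
    extract_features()
  re <- evaluate_milk_lopo(easy, head = "lda", n_components = 5, seed = 1)
  expect_equal(sum(re$confusion) - sum(diag(re$confusion)), 0)

  # a roster with a single-product class is rejected
  solo <- m[m$product_id != "almond_p2", ]
  expect_error(evaluate_milk_lopo(solo), class = "etongue_protocol_error")
})

test_that("agglomerative clustering recovers planted groups and ARI calibrates", {
  expect_equal(adjusted_rand_index(rep(1:4, 10), rep(1:4, 10)), 1)
  # label permutation does not matter
  expect_equal(adjusted_rand_index(rep(1:4, 10), rep(c(4, 3, 1, 2), 10)), 1)
  # random labelings score near zero (permutation oracle over 100 draws)
  set.seed(8)
  truth <- rep(1:4, each = 10)
  aris <- replicate(100, adjusted_rand_index(sample(truth), truth))
  expect_lt(abs(mean(aris)), 0.1)

  d <- featurized_fixture("custom", seed = 6, separation = 1.5)
  cl <- cluster_fingerprints(d, n_clusters = 3, n_components = 2)
  expect_equal(cl$ari, 1)
  expect_error(cluster_fingerprints(d[1:2, ], n_clusters = 4),
               class = "etongue_invalid_argument")
  expect_s3_class(autoplot(cl), "ggplot")
})

test_that("accuracy-distribution comparison is a symmetric two-sided t-test", {
  a <- c(0.9, 0.92, 0.91, 0.93)
  b <- c(0.5, 0.52, 0.51, 0.49)
  p <- compare_accuracy_distributions(a, b)
  expect_lt(p, 0.001)
  expect_equal(p, compare_accuracy_distributions(b, a))
  # closed-form pooled-variance oracle
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(p, 2 * pt(-abs(tstat), df = 6), tolerance = 1e-12)

  expect_equal(compare_accuracy_distributions(c(1, 1), c(1, 1)), 1)
  expect_equal(compare_accuracy_distributions(c(1, 1), c(0, 0)), 0)
  expect_error(compare_accuracy_distributions(1, c(0.5, 0.6)),
               class = "etongue_invalid_argument")
})
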