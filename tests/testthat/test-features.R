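test_that("builtin extractor is a pure 1280-dim function of the pixels", {
  img <- random_image(1)
  v1 <- builtin_extract(img)
  v2 <- builtin_extract(img)
  expect_length(v1, 1280)
  expect_identical(v1, v2)

  # constant image: all grid standard deviations are zero and the DCT
  # energy sits entirely in the DC coefficient
  const <- render_image(matrix(-1, 48, 48))  # renders as all-zero pixels
  vc <- builtin_extract(const)
  grid <- matrix(vc[1:256], nrow = 4)        # stats x cells
  expect_true(all(grid[2, ] == 0))           # per-cell std
  dct_block <- matrix(vc[257:1280], 32, 32)
  expect_true(all(abs(dct_block[-1]) < 1e-9))

  # a single pixel flip changes the embedding
  img2 <- unclass(img)
  img2[5, 5, ] <- (img2[5, 5, ] + 100) %% 256
  img2 <- structure(img2, class = "rendered_image")
  expect_false(identical(v1, builtin_extract(img2)))
})

test_that("the DCT block matches the direct cosine-sum oracle", {
  img <- random_image(7, 48)
  v <- builtin_extract(img)
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)
  n <- 48
  dct_coef <- function(k, l) {  # orthonormal DCT-II, explicit double sum
    ck <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    cl <- if (l == 0) sqrt(1 / n) else sqrt(2 / n)
    s <- 0
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      s <- s + gray[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * k / (2 * n)) *
        cos(pi * (2 * j + 1) * l / (2 * n))
    }
    ck * cl * s
  }
  block <- matrix(v[257:1280], 32, 32)
  for (k in c(0, 1, 5)) for (l in c(0, 2, 7)) {
    expect_equal(block[k + 1, l + 1], dct_coef(k, l), tolerance = 1e-9)
  }
})

test_that("grid statistics match direct recomputation", {
  img <- random_image(3, 48)
  v <- builtin_extract(img)
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)
  # cell (2, 3) in row-major order is entry 8 + 3 = 11
  cell <- gray[7:12, 13:18]
  idx <- ((2 - 1) * 8 + 3 - 1) * 4
  expect_equal(v[idx + 1], mean(cell))
  expect_equal(v[idx + 2], sd(as.vector(cell)))
  expect_equal(v[idx + 3], min(cell))
  expect_equal(v[idx + 4], max(cell))
})

test_that("backbone adapter enforces its contract without weights", {
  expect_length(backbone_registry(), 12)
  spec <- extractor_spec("vit_base_384")
  expect_equal(spec$input_resolution, 384)
  expect_equal(spec$kind, "external-backbone")

  img224 <- random_image(1, 224)
  expect_error(backbone_extract(img224, spec),
               class = "etongue_invalid_argument")  # resolution mismatch
  img384 <- random_image(1, 384)
  expect_error(backbone_extract(img384, spec),
               class = "etongue_capability_error")  # no weights shipped
  expect_error(extractor_spec("not_a_backbone"),
               class = "etongue_invalid_argument")
  # the pipeline still runs with the builtin extractor
  d <- featurized_fixture("custom", seed = 1)
  expect_true(all(lengths(d$embedding) == 1280))
})

test_that("PCA honors rank, ordering and the component sweep", {
  set.seed(2)
  base <- matrix(rnorm(30 * 2), 30, 2)
  x <- base %*% matrix(rnorm(2 * 40), 2, 40)  # rank-2 embeddings
  m2 <- fit_pca(x, 2)
  expect_gte(sum(m2$explained_variance_ratio), 0.999)

  y <- matrix(rnorm(30 * 40), 30, 40)
  for (k in c(5, 10, 15, 20, 25)) {
    m <- fit_pca(y, k)
    expect_equal(m$n_components, k)
    expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
    expect_lte(sum(m$explained_variance_ratio), 1 + 1e-12)
  }
  expect_error(fit_pca(y, 31), class = "etongue_invalid_argument")
})

test_that("PCA projection reproduces fit scores and improves with k", {
  set.seed(5)
  x <- matrix(rnorm(40 * 60), 40, 60)
  m <- fit_pca(x, 10)
  scores <- transform_pca(m, x)
  ref <- prcomp(x, center = TRUE, rank. = 10)
  expect_equal(abs(scores), abs(ref$x), tolerance = 1e-8, ignore_attr = TRUE)

  # a zero-variance feature contributes nothing to any score
  x0 <- cbind(x, 3)
  m0 <- fit_pca(x0, 5)
  expect_true(all(abs(m0$rotation[61, ]) < 1e-9))

  # reconstruction error decreases as k grows
  recon_err <- function(k) {
    mk <- fit_pca(x, k)
    sk <- transform_pca(mk, x)
    xh <- sk %*% t(mk$rotation) + matrix(mk$center, 40, 60, byrow = TRUE)
    sum((x - xh)^2)
  }
  expect_lt(recon_err(25), recon_err(5))

  expect_error(transform_pca(m, matrix(0, 3, 10)),
               class = "etongue_invalid_argument")
  expect_equal(nrow(tidy(m)), 10)
})

test_that("the PCA basis never sees held-out embeddings", {
  d <- featurized_fixture("custom", seed = 4)
  train <- d[1:12, ]
  m1 <- fit_pca(train, 4)
  # perturbing data outside the training rows cannot change the basis
  d2 <- d
  d2$embedding[[15]] <- d2$embedding[[15]] + 100
  m2 <- fit_pca(d2[1:12, ], 4)
  expect_identical(m1$rotation, m2$rotation)
  expect_identical(m1$center, m2$center)
})

test_that("well-separated classes separate in PC space (positive silhouette)", {
  sil <- sapply(1:3, function(s) {
    d <- featurized_fixture("custom", seed = 20 + s, separation = 1.5)
    sc <- transform_pca(fit_pca(d, 2), etongue:::embedding_matrix(d))
    # mean silhouette width on PC1-PC2
    dm <- as.matrix(dist(sc))
    mean(sapply(seq_len(nrow(d)), function(i) {
      own <- d$label == d$label[i]
      a <- mean(dm[i, own & seq_len(nrow(d)) != i])
      b <- min(tapply(dm[i, !own], d$label[!own], mean))
      (b - a) / max(a, b)
    }))
  })
  expect_gt(mean(sil), 0)
})
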