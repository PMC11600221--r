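#' Classification-head specification
#'
#' The lightweight classifiers trained on principal-component scores. Fixed
#' hyperparameters follow the pipeline's conventions: 50 trees for the
#' random forest and 3 neighbours for KNN; the other heads use their
#' library defaults. `"random"` is the uniform-random baseline predictor
#' used to establish chance level.
#'
#' @param name One of `"rf"`, `"lda"`, `"knn"`, `"svm"`, `"et"`, `"xgb"`,
#'   `"random"` (case-insensitive).
#' @param ... Hyperparameter overrides (e.g. `ntree`, `k`).
#' @return A list of class `"head_spec"`.
#' @export
#' @examples
#' head_spec("rf")$hyperparameters$ntree  # 50
head_spec <- function(name, ...) {
  name <- tolower(name)
  defaults <- list(
    rf = list(ntree = 50),
    lda = list(),
    knn = list(k = 3),
    svm = list(),
    et = list(num.trees = 100),
    xgb = list(nrounds = 100, eta = 0.3, max_depth = 6),
    random = list()
  )
  if (!name %in% names(defaults)) {
    stop_invalid(sprintf("unknown head '%s'; use rf, lda, knn, svm, et, xgb or random", name))
  }
  hp <- utils::modifyList(defaults[[name]], list(...))
  structure(list(name = name, hyperparameters = hp), class = "head_spec")
}

as_head_spec <- function(head) {
  if (inherits(head, "head_spec")) head else head_spec(head)
}

#' Train a classification head on score vectors
#'
#' @param spec A [head_spec()] or head name.
#' @param x Numeric matrix of principal-component scores (n x k).
#' @param y Class labels (coerced to factor; at least two classes).
#' @param seed Integer seed for the stochastic heads.
#' @return A fitted object of class `"et_head"` supporting
#'   [predict_head()].
#' @export
train_head <- function(spec, x, y, seed = 1) {
  spec <- as_head_spec(spec)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop_invalid("training labels must contain at least two classes")
  if (nrow(x) != length(y)) stop_invalid("`x` rows must match `y` length")
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    rf = with_seed(seed, randomForest::randomForest(x, y, ntree = hp$ntree)),
    lda = MASS::lda(x, grouping = y),
    knn = list(train = x, cl = y, k = hp$k),
    svm = e1071::svm(x, y),
    et = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = hp$num.trees,
      splitrule = "extratrees", replace = FALSE, sample.fraction = 1,
      seed = seed, num.threads = 1
    ),
    xgb = with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softmax", num_class = nlevels(y),
                      eta = hp$eta, max_depth = hp$max_depth, nthread = 1),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    }),
    random = list()
  )
  structure(list(spec = spec, fit = fit, levels = levels(y), seed = seed),
            class = "et_head")
}

# 3-NN vote with ties broken by the nearest neighbour's label
knn_predict <- function(fit, newx) {
  apply(newx, 1L, function(q) {
    d2 <- colSums((t(fit$train) - q)^2)
    nn <- order(d2)[seq_len(min(fit$k, length(d2)))]
    votes <- table(fit$cl[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else {
      as.character(fit$cl[nn[match(TRUE, as.character(fit$cl[nn]) %in% top)]])
    }
  })
}

#' Predict class labels with a fitted head
#'
#' @param head An `"et_head"` from [train_head()].
#' @param newx Matrix of score vectors.
#' @return Character vector of predicted labels.
#' @export
predict_head <- function(head, newx) {
  stopifnot(inherits(head, "et_head"))
  newx <- as.matrix(newx)
  out <- switch(head$spec$name,
    rf = as.character(predict(head$fit, newx)),
    lda = as.character(predict(head$fit, newx)$class),
    knn = knn_predict(head$fit, newx),
    svm = as.character(predict(head$fit, newx)),
    et = as.character(predict(head$fit, data = as.data.frame(newx),
                              num.threads = 1)$predictions),
    xgb = {
      p <- predict(head$fit, xgboost::xgb.DMatrix(newx))
      head$levels[p + 1L]
    },
    random = sample(head$levels, nrow(newx), replace = TRUE)
  )
  unname(out)
}

# ---- evaluation reports -------------------------------------------------

new_eval_report <- function(accuracies, confusion, protocol, seeds,
                            head, n_components, n_test_total, n_correct) {
  structure(
    list(
      per_rep = tibble(rep = seq_along(accuracies), seed = seeds,
                       accuracy = accuracies),
      mean_accuracy = n_correct / n_test_total,
      sd_accuracy = if (length(accuracies) > 1) sd(accuracies) else 0,
      confusion = confusion,
      protocol = protocol,
      head = head,
      n_components = n_components,
      n_test_total = n_test_total,
      n_correct = n_correct
    ),
    class = "et_eval"
  )
}

#' @export
print.et_eval <- function(x, ...) {
  cat(sprintf("<et_eval> %s | head=%s, %d PCs\n", x$protocol, x$head, x$n_components))
  cat(sprintf("  accuracy %.1f%% +/- %.1f%% over %d iteration(s) (%d/%d pooled)\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              nrow(x$per_rep), x$n_correct, x$n_test_total))
  invisible(x)
}

#' @export
tidy.et_eval <- function(x, ...) x$per_rep

#' @export
glance.et_eval <- function(x, ...) {
  tibble(protocol = x$protocol, head = x$head, n_components = x$n_components,
         n_reps = nrow(x$per_rep), mean_accuracy = x$mean_accuracy,
         sd_accuracy = x$sd_accuracy, n_test_total = x$n_test_total,
         n_correct = x$n_correct)
}

confusion_matrix <- function(truth, pred, levels) {
  table(truth = factor(truth, levels = levels),
        predicted = factor(pred, levels = levels))
}

fit_and_predict <- function(data, train_idx, test_idx, head, n_components,
                            seed, train_labels = NULL) {
  train <- data[train_idx, , drop = FALSE]
  test <- data[test_idx, , drop = FALSE]
  y_train <- train_labels %||% train$label
  pca <- fit_pca(embedding_matrix(train), n_components)
  fitted <- train_head(head, transform_pca(pca, embedding_matrix(train)),
                       y_train, seed = seed)
  predict_head(fitted, transform_pca(pca, embedding_matrix(test)))
}

#' Repeated stratified five-fold evaluation
#'
#' The identification-task protocol: 50 repetitions of a random
#' stratified split into training (80%) and test (20%) sets. Within every
#' repetition the PCA basis is fitted on the training embeddings only, the
#' head is trained on the training scores and accuracy is measured on the
#' held-out 20%. Mean and standard deviation over the repetitions are
#' reported.
#'
#' @param data A featurized tibble (columns `label`, `embedding`).
#' @param head A head name or [head_spec()].
#' @param n_components PCA dimensionality.
#' @param reps Number of repetitions (default 50).
#' @param seed Root seed; repetition r uses `seed + r - 1`.
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @return An `"et_eval"` report.
#' @export
evaluate_kfold <- function(data, head = "lda", n_components = 20, reps = 50,
                           seed = 1, test_fraction = 0.2) {
  stopifnot(is.data.frame(data), all(c("label", "embedding") %in% names(data)))
  head <- as_head_spec(head)
  reps <- check_count(reps, "reps")
  counts <- table(data$label)
  if (any(counts < 5)) {
    stop_protocol("every class needs at least 5 instances for the 80/20 protocol")
  }
  lv <- sort(unique(data$label))
  confusion <- confusion_matrix(character(), character(), lv)
  accuracies <- numeric(reps)
  seeds <- seed + seq_len(reps) - 1L
  for (r in seq_len(reps)) {
    test_idx <- with_seed(seeds[r], {
      unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
        sample(idx, max(1L, floor(length(idx) * test_fraction)))
      }), use.names = FALSE)
    })
    train_idx <- setdiff(seq_len(nrow(data)), test_idx)
    pred <- with_seed(seeds[r] + 500000L,
      fit_and_predict(data, train_idx, test_idx, head, n_components, seeds[r]))
    truth <- data$label[test_idx]
    accuracies[r] <- mean(pred == truth)
    confusion <- confusion + confusion_matrix(truth, pred, lv)
  }
  new_eval_report(accuracies, confusion,
                  sprintf("repeated stratified %d%%/%d%% split x %d",
                          round(100 * (1 - test_fraction)),
                          round(100 * test_fraction), reps),
                  seeds, head$name, n_components,
                  n_test_total = sum(confusion), n_correct = sum(diag(confusion)))
}

#' Leave-one-class-out evaluation for the sugar task
#'
#' Tests simultaneous sugar-type and concentration-level assignment. For
#' each of the four extreme cells (each sugar at 2.5 and 10 % w/w) all of
#' its replicates are held out; the mid-level (5 % w/w) measurements are
#' relabeled `low` when the held-out class is the 2.5 % level and `high`
#' when it is the 10 % level, so training always covers the four categories
#' glucose/sucrose x low/high. Predictions are pooled over the four
#' iterations (40 test measurements at the default layout).
#'
#' @param data Featurized sugar-task tibble (columns `sugar`, `level_pct`,
#'   `embedding`).
#' @param head,n_components,seed As in [evaluate_kfold()].
#' @return An `"et_eval"` report; `per_rep` holds the four per-iteration
#'   accuracies and `mean_accuracy` the pooled accuracy.
#' @export
evaluate_sugar_locov <- function(data, head = "lda", n_components = 20, seed = 1) {
  stopifnot(is.data.frame(data),
            all(c("sugar", "level_pct", "embedding") %in% names(data)))
  head <- as_head_spec(head)
  levels_present <- sort(unique(data$level_pct))
  if (!all(c(2.5, 5, 10) %in% levels_present)) {
    stop_protocol("sugar protocol needs all three concentration levels (2.5, 5, 10)")
  }
  lv <- c("glucose_low", "glucose_high", "sucrose_low", "sucrose_high")
  confusion <- confusion_matrix(character(), character(), lv)
  iters <- expand.grid(sugar = sort(unique(data$sugar)), level = c(2.5, 10),
                       stringsAsFactors = FALSE)
  accuracies <- numeric(nrow(iters))
  seeds <- seed + seq_len(nrow(iters)) - 1L
  for (i in seq_len(nrow(iters))) {
    s <- iters$sugar[i]; l <- iters$level[i]
    test_idx <- which(data$sugar == s & data$level_pct == l)
    train_idx <- setdiff(seq_len(nrow(data)), test_idx)
    mid_as <- if (l == 2.5) "low" else "high"
    relabel <- function(sugar, level) {
      ifelse(level == 2.5, paste0(sugar, "_low"),
             ifelse(level == 10, paste0(sugar, "_high"),
                    paste0(sugar, "_", mid_as)))
    }
    train_labels <- relabel(data$sugar[train_idx], data$level_pct[train_idx])
    pred <- with_seed(seeds[i] + 500000L,
      fit_and_predict(data, train_idx, test_idx, head, n_components, seeds[i],
                      train_labels = train_labels))
    truth <- relabel(data$sugar[test_idx], data$level_pct[test_idx])
    accuracies[i] <- mean(pred == truth)
    confusion <- confusion + confusion_matrix(truth, pred, lv)
  }
  new_eval_report(accuracies, confusion, "sugar leave-one-class-out (pooled)",
                  seeds, head$name, n_components,
                  n_test_total = sum(confusion), n_correct = sum(diag(confusion)))
}

#' Leave-one-product-out evaluation for the milk task
#'
#' One iteration per commercial product: all of its replicates are held
#' out, the head is trained on the remaining products and predicts the
#' protein source among the five classes. Every source class must be
#' represented by at least two products, so the held-out product's class is
#' always still present in training. Accuracy is pooled over products.
#'
#' @param data Featurized milk-task tibble (columns `label`, `product_id`,
#'   `embedding`).
#' @param head,n_components,seed As in [evaluate_kfold()].
#' @return An `"et_eval"` report; `per_rep` holds per-product accuracies
#'   and `mean_accuracy` the pooled accuracy.
#' @export
evaluate_milk_lopo <- function(data, head = "lda", n_components = 20, seed = 1) {
  stopifnot(is.data.frame(data),
            all(c("label", "product_id", "embedding") %in% names(data)))
  head <- as_head_spec(head)
  prod_class <- unique(data[, c("product_id", "label")])
  per_class <- table(prod_class$label)
  if (any(per_class < 2)) {
    stop_protocol(sprintf(
      "source class(es) with a single product: %s; leave-one-product-out would drop the class from training",
      paste(names(per_class)[per_class < 2], collapse = ", ")
    ))
  }
  products <- sort(unique(data$product_id))
  lv <- sort(unique(data$label))
  confusion <- confusion_matrix(character(), character(), lv)
  accuracies <- numeric(length(products))
  seeds <- seed + seq_along(products) - 1L
  for (i in seq_along(products)) {
    test_idx <- which(data$product_id == products[i])
    train_idx <- setdiff(seq_len(nrow(data)), test_idx)
    pred <- with_seed(seeds[i] + 500000L,
      fit_and_predict(data, train_idx, test_idx, head, n_components, seeds[i]))
    truth <- data$label[test_idx]
    accuracies[i] <- mean(pred == truth)
    confusion <- confusion + confusion_matrix(truth, pred, lv)
  }
  new_eval_report(accuracies, confusion, "milk leave-one-product-out (pooled)",
                  seeds, head$name, n_components,
                  n_test_total = sum(confusion), n_correct = sum(diag(confusion)))
}

#' Agglomerative clustering of fingerprints scored by ARI
#'
#' Reduces the embeddings to principal-component scores, clusters them by
#' agglomerative hierarchical clustering with Euclidean distance and Ward
#' linkage into a predetermined number of groups, and scores agreement with
#' the true labels by the Adjusted Rand Index (1 for perfect recovery,
#' about 0 for random labeling).
#'
#' @param data Featurized tibble (columns `label`, `embedding`).
#' @param n_clusters Number of groups to cut the tree into (default 4).
#' @param n_components PCA dimensionality of the clustered scores.
#' @return A list of class `"et_clustering"`: `ari`, `assignment`,
#'   `scores`, `labels`, `n_clusters`.
#' @export
cluster_fingerprints <- function(data, n_clusters = 4, n_components = 5) {
  stopifnot(is.data.frame(data), all(c("label", "embedding") %in% names(data)))
  n_clusters <- check_count(n_clusters, "n_clusters")
  if (nrow(data) < n_clusters) {
    stop_invalid("fewer samples than requested clusters")
  }
  pca <- fit_pca(embedding_matrix(data), n_components)
  scores <- transform_pca(pca, embedding_matrix(data))
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  assignment <- stats::cutree(hc, k = n_clusters)
  structure(
    list(ari = adjusted_rand_index(assignment, data$label),
         assignment = assignment, scores = scores, labels = data$label,
         n_clusters = n_clusters),
    class = "et_clustering"
  )
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' permutation), approximately 0 for independent random labelings.
#'
#' @param a,b Two label vectors of equal length.
#' @return A single number.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' @export
print.et_clustering <- function(x, ...) {
  cat(sprintf("<et_clustering> %d clusters over %d samples, ARI = %.3f\n",
              x$n_clusters, length(x$assignment), x$ari))
  invisible(x)
}

#' @export
glance.et_clustering <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, n = length(x$assignment), ari = x$ari)
}

#' Compare two accuracy distributions
#'
#' Two-sided two-sample t-test (pooled variance) on per-repetition accuracy
#' vectors, as used to judge whether augmentation shifts the accuracy
#' distribution; differences are called significant below p = 0.05. Two
#' zero-variance vectors with equal means return p = 1 by convention (and
#' p = 0 when their means differ).
#'
#' @param a,b Numeric accuracy vectors, each of length >= 2.
#' @return The two-sided p-value.
#' @export
#' @examples
#' compare_accuracy_distributions(c(0.9, 0.91, 0.92), c(0.5, 0.52, 0.51))
compare_accuracy_distributions <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("both accuracy vectors need length >= 2")
  }
  if (var(a) == 0 && var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  t.test(a, b, var.equal = TRUE)$p.value
}
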