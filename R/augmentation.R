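#' Mixing specification for pixel-wise augmentation
#'
#' Synthetic fingerprints are convex pixel-wise combinations of two real
#' images from different classes, `s = a * primary + b * donor` with
#' `a + b = 1` and `a > 0.5`, so the synthetic sample stays dominated by
#' (and labeled as) its primary class. The mixing ratios used in practice
#' are a/b of 0.95/0.05 down to 0.75/0.25; 0.85/0.15 is the default since
#' the ratio has little effect on downstream accuracy.
#'
#' @param a Primary weight, strictly between 0.5 and 1.
#' @param target_per_class Total training instances per class after
#'   augmentation (real + synthetic), default 50.
#' @param seed Integer seed for primary/donor draws.
#' @return A list of class `"mix_spec"` (with `b = 1 - a`).
#' @export
mix_spec <- function(a = 0.85, target_per_class = 50, seed = 1) {
  a <- check_scalar(a, "a")
  if (a <= 0.5 || a >= 1) stop_invalid("`a` must lie strictly between 0.5 and 1")
  structure(list(a = a, b = 1 - a,
                 target_per_class = check_count(target_per_class, "target_per_class"),
                 seed = check_count(seed, "seed", 0L)),
            class = "mix_spec")
}

#' Mix two fingerprint images pixel-wise
#'
#' Computes `s = a * primary + (1 - a) * donor` per pixel (rounded
#' half-to-even back to 0..255), producing a synthetic sample labeled with
#' the primary's class. The two parents must come from different classes
#' and share a resolution. Every synthetic pixel lies between its parents'
#' values.
#'
#' @param primary,donor `"rendered_image"` arrays of equal shape.
#' @param a Primary weight in (0.5, 1).
#' @param primary_class,donor_class Class identifiers; must differ.
#' @return A `"rendered_image"` with attributes `parent_class`,
#'   `donor_class` and `a_used`.
#' @export
mix_images <- function(primary, donor, a, primary_class, donor_class) {
  a <- check_scalar(a, "a")
  if (a <= 0.5 || a >= 1) stop_invalid("`a` must lie strictly between 0.5 and 1")
  if (identical(primary_class, donor_class)) {
    stop_invalid("primary and donor must come from different classes")
  }
  if (!identical(dim(primary), dim(donor))) {
    stop_invalid("primary and donor images must share a shape")
  }
  mixed <- round(a * unclass(primary) + (1 - a) * unclass(donor))
  mixed <- pmin(255, pmax(0, mixed))
  structure(array(mixed, dim = dim(primary)),
            class = "rendered_image",
            resolution = attr(primary, "resolution") %||% dim(primary)[1],
            channel_mode = attr(primary, "channel_mode"),
            parent_class = primary_class, donor_class = donor_class,
            a_used = a, synthetic = TRUE)
}

#' Augment a training set to a fixed count per class
#'
#' For every class, adds synthetic mixed images until the class holds
#' `target_per_class` training instances (real + synthetic). Primaries are
#' drawn (seeded) from the class's real images; donors from the real images
#' of a uniformly chosen other class, varying type and instance. Real rows
#' are never altered or removed; classes already at or above the target get
#' no synthetic samples.
#'
#' @param train A tibble with columns `label` and `image` (real training
#'   shots only).
#' @param spec A [mix_spec()].
#' @return A tibble of real plus synthetic rows with columns `sample_id`,
#'   `label`, `image`, `synthetic`, `parent_id`, `donor_id`, `a_used`.
#' @export
augment_training_set <- function(train, spec = mix_spec()) {
  stopifnot(is.data.frame(train), all(c("label", "image") %in% names(train)))
  stopifnot(inherits(spec, "mix_spec"))
  classes <- sort(unique(train$label))
  if (length(classes) < 2) {
    stop_invalid("augmentation needs at least two classes of real images")
  }
  ids <- if ("sample_id" %in% names(train)) train$sample_id else
    sprintf("real_%03d", seq_len(nrow(train)))
  real <- tibble(sample_id = ids, label = train$label, image = train$image,
                 synthetic = FALSE, parent_id = NA_character_,
                 donor_id = NA_character_, a_used = NA_real_)
  syn_rows <- with_seed(spec$seed, {
    out <- list()
    for (cl in classes) {
      own <- which(real$label == cl)
      other <- which(real$label != cl)
      n_syn <- spec$target_per_class - length(own)
      if (n_syn <= 0) next
      for (s in seq_len(n_syn)) {
        p <- own[sample.int(length(own), 1L)]
        d <- other[sample.int(length(other), 1L)]
        img <- mix_images(real$image[[p]], real$image[[d]], spec$a,
                          primary_class = cl, donor_class = real$label[d])
        out[[length(out) + 1L]] <- tibble(
          sample_id = sprintf("syn_%s_%03d", cl, s), label = cl,
          image = list(img), synthetic = TRUE,
          parent_id = real$sample_id[p], donor_id = real$sample_id[d],
          a_used = spec$a
        )
      }
    }
    out
  })
  dplyr::bind_rows(c(list(real), syn_rows))
}

#' Few-shot training experiment with and without augmentation
#'
#' Measures how many labeled measurements per class the pipeline needs. In
#' each repetition, `k_shots` instances per class are sampled for training
#' and all remaining real measurements form the test set. Both conditions
#' are then run on identical splits: plain (the k shots only) and augmented
#' (the shots mixed up to `spec$target_per_class` instances per class, the
#' synthetic images re-featurized). PCA uses `n_components` scores
#' (10 by default, reflecting the reduced training size), the head is
#' trained per condition and test accuracy recorded; the two accuracy
#' distributions are compared with a two-sided t-test.
#'
#' @param data Featurized tibble with both `image` and `embedding` columns.
#' @param head Head name or [head_spec()].
#' @param k_shots Shots per class (3, 5 or 7 in the standard protocol).
#' @param spec A [mix_spec()].
#' @param reps Number of random splits (default 50).
#' @param n_components PCA dimensionality (default 10).
#' @param seed Root seed.
#' @param extractor Extractor for the synthetic images.
#' @return A list of class `"et_fewshot"`: `plain` and `augmented`
#'   `"et_eval"` reports, `p_value`, `k_shots`, `spec`.
#' @export
fewshot_experiment <- function(data, head = "lda", k_shots = 3,
                               spec = mix_spec(), reps = 50,
                               n_components = 10, seed = 1,
                               extractor = "builtin") {
  stopifnot(is.data.frame(data),
            all(c("label", "image", "embedding") %in% names(data)))
  head <- as_head_spec(head)
  k_shots <- check_count(k_shots, "k_shots")
  counts <- table(data$label)
  if (any(counts <= k_shots)) {
    stop_protocol("every class needs more than `k_shots` instances (some must remain for testing)")
  }
  lv <- sort(unique(data$label))
  acc <- matrix(0, nrow = reps, ncol = 2,
                dimnames = list(NULL, c("plain", "augmented")))
  conf_plain <- confusion_matrix(character(), character(), lv)
  conf_aug <- conf_plain
  seeds <- seed + seq_len(reps) - 1L
  ex_spec <- if (inherits(extractor, "extractor_spec")) extractor else extractor_spec(extractor)

  for (r in seq_len(reps)) {
    train_idx <- with_seed(seeds[r], {
      unlist(lapply(split(seq_len(nrow(data)), data$label),
                    function(idx) sample(idx, k_shots)), use.names = FALSE)
    })
    test_idx <- setdiff(seq_len(nrow(data)), train_idx)
    truth <- data$label[test_idx]
    test_emb <- embedding_matrix(data[test_idx, ])

    # plain condition: the k shots only
    pred_p <- with_seed(seeds[r] + 500000L,
      fit_and_predict(data, train_idx, test_idx, head, n_components, seeds[r]))
    acc[r, "plain"] <- mean(pred_p == truth)
    conf_plain <- conf_plain + confusion_matrix(truth, pred_p, lv)

    # augmented condition: mix up to target_per_class, re-featurize synthetics
    aug <- augment_training_set(
      data[train_idx, c("sample_id", "label", "image")],
      mix_spec(a = spec$a, target_per_class = spec$target_per_class,
               seed = derive_seed(spec$seed, r))
    )
    aug_emb <- rbind(
      embedding_matrix(data[train_idx, ])[match(
        aug$sample_id[!aug$synthetic], data$sample_id[train_idx]), , drop = FALSE],
      do.call(rbind, purrr::map(aug$image[aug$synthetic],
                                cached_extract, spec = ex_spec))
    )
    aug_labels <- c(aug$label[!aug$synthetic], aug$label[aug$synthetic])
    pred_a <- with_seed(seeds[r] + 900000L, {
      pca <- fit_pca(aug_emb, n_components)
      fitted <- train_head(head, transform_pca(pca, aug_emb), aug_labels,
                           seed = seeds[r])
      predict_head(fitted, transform_pca(pca, test_emb))
    })
    acc[r, "augmented"] <- mean(pred_a == truth)
    conf_aug <- conf_aug + confusion_matrix(truth, pred_a, lv)
  }

  plain <- new_eval_report(acc[, "plain"], conf_plain,
                           sprintf("%d-shot x %d reps (no augmentation)", k_shots, reps),
                           seeds, head$name, n_components,
                           n_test_total = sum(conf_plain),
                           n_correct = sum(diag(conf_plain)))
  augmented <- new_eval_report(acc[, "augmented"], conf_aug,
                               sprintf("%d-shot x %d reps (mixup to %d/class, a = %.2f)",
                                       k_shots, reps, spec$target_per_class, spec$a),
                               seeds, head$name, n_components,
                               n_test_total = sum(conf_aug),
                               n_correct = sum(diag(conf_aug)))
  structure(
    list(plain = plain, augmented = augmented,
         p_value = compare_accuracy_distributions(acc[, "plain"], acc[, "augmented"]),
         k_shots = k_shots, spec = spec),
    class = "et_fewshot"
  )
}

#' @export
print.et_fewshot <- function(x, ...) {
  cat(sprintf("<et_fewshot> %d-shot, head=%s\n", x$k_shots, x$plain$head))
  cat(sprintf("  plain     %.1f%% +/- %.1f%%\n",
              100 * mean(x$plain$per_rep$accuracy), 100 * x$plain$sd_accuracy))
  cat(sprintf("  augmented %.1f%% +/- %.1f%%\n",
              100 * mean(x$augmented$per_rep$accuracy), 100 * x$augmented$sd_accuracy))
  cat(sprintf("  two-sided t-test p = %.3g%s\n", x$p_value,
              if (x$p_value < 0.05) " (*)" else ""))
  invisible(x)
}

#' @export
tidy.et_fewshot <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$plain$per_rep, condition = "plain"),
    dplyr::mutate(x$augmented$per_rep, condition = "augmented")
  )
}

#' @export
glance.et_fewshot <- function(x, ...) {
  tibble(k_shots = x$k_shots, head = x$plain$head,
         mean_plain = mean(x$plain$per_rep$accuracy),
         mean_augmented = mean(x$augmented$per_rep$accuracy),
         sd_plain = x$plain$sd_accuracy, sd_augmented = x$augmented$sd_accuracy,
         p_value = x$p_value)
}
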