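#' @export
autoplot.et_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_rep, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      title = sprintf("%s — %s head, %d PCs", object$protocol, object$head,
                      object$n_components),
      subtitle = sprintf("mean %.1f%% +/- %.1f%%", 100 * object$mean_accuracy,
                         100 * object$sd_accuracy),
      x = "test accuracy", y = "repetitions"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.et_fewshot <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$accuracy,
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      title = sprintf("%d-shot training, %s head", object$k_shots,
                      object$plain$head),
      subtitle = sprintf("two-sided t-test p = %.3g%s", object$p_value,
                         if (object$p_value < 0.05) " (*)" else ""),
      x = NULL, y = "test accuracy"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.et_clustering <- function(object, ...) {
  df <- tibble(
    pc1 = object$scores[, 1],
    pc2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0,
    cluster = factor(object$assignment),
    label = object$labels
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$cluster,
                                   shape = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      title = sprintf("Ward agglomerative clustering (ARI = %.2f)", object$ari),
      x = "PC1", y = "PC2"
    ) +
    ggplot2::theme_minimal()
}
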