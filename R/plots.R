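#' Plot an evaluation report
#'
#' Bar chart of precision, recall and F1.
#'
#' @param object A `radcoder_eval`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot radcoder_eval
autoplot.radcoder_eval <- function(object, ...) {
  df <- tibble(metric = factor(c("precision", "recall", "F1"),
                               levels = c("precision", "recall", "F1")),
               value = c(object$precision, object$recall, object$f1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05), expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Coding evaluation") +
    ggplot2::theme_minimal()
}

#' Plot the MLP training loss history
#'
#' @param object A trained `radcoder_mlp`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot radcoder_mlp
autoplot.radcoder_mlp <- function(object, ...) {
  hist <- object$training_meta$loss_history
  if (is.null(hist)) abort("Model carries no training history; train it first.")
  df <- tibble(epoch = seq_along(hist), loss = hist)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training cross-entropy",
                  title = "Ensemble training") +
    ggplot2::theme_minimal()
}

#' Plot score distributions of labelled pairs
#'
#' Densities of the four similarity scores by label — the picture of how
#' separable synonym and non-synonym pairs are for each scorer alone.
#'
#' @param scores Tibble from [score_pairs()] with a `label` column.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scores) {
  long <- tidyr::pivot_longer(scores, cols = c("lev", "jac", "cbow", "wup"),
                              names_to = "score", values_to = "value")
  long$label <- factor(long$label, levels = c(0, 1),
                       labels = c("non-synonym", "synonym"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$label)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 30) +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "similarity", y = "pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
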