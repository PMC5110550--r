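# ggplot2 autoplot() methods for the package's result objects.

#' @export
autoplot.te_support_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
      y = .data$n)) +
    ggplot2::geom_col(width = object$bin_end[1] - object$bin_start[1],
      fill = "grey35") +
    ggplot2::labs(x = "supporting reads", y = "calls",
      title = "Supporting-read distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_freq_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
    ggplot2::aes(x = .data$tissue, y = .data$n, fill = .data$bin)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::labs(y = "% of insertions", x = NULL, fill = "panel frequency",
      subtitle = sprintf("KS D = %.3f, p = %.3g", object$statistic,
        object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_ks_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
    ggplot2::aes(x = .data$log10_expression, colour = .data$tissue)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "log10(count + pseudocount)", y = "ECDF",
      subtitle = sprintf("KS D = %.3f, p = %.3g", object$statistic,
        object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-family unique-insertion counts of a cohort summary
#'
#' @param summary A `te_cohort_summary` with the per-family breakdown.
#' @return A ggplot object.
#' @export
plot_unique_counts <- function(summary) {
  stopifnot(inherits(summary, "te_cohort_summary"))
  ggplot2::ggplot(tidy(summary),
    ggplot2::aes(x = .data$family, y = .data$n_unique,
      fill = .data$tissue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "unique insertions", fill = NULL,
      title = "Tissue-private insertions by family") +
    ggplot2::theme_minimal()
}
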