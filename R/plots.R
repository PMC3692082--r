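#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_point
#'   facet_wrap labs theme_minimal geom_boxplot
#' @export
ggplot2::autoplot

#' Plot the distribution of target probabilities per label
#'
#' @param object A `mirset_result` from [predict_targets()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirset_result <- function(object, bins = 30, ...) {
  labels <- setdiff(names(object), c("gene", "difference", "p_value",
                                     "mean_difference", "p_adjusted",
                                     "differential"))
  labels <- labels[!startsWith(labels, "rank_")]
  long <- tidyr::pivot_longer(as_tibble(object)[, c("gene", labels)],
                              -"gene", names_to = "label",
                              values_to = "probability")
  ggplot(long, aes(x = .data$probability)) +
    geom_histogram(bins = bins, fill = "grey30") +
    facet_wrap(~label) +
    labs(x = "target probability", y = "genes") +
    theme_minimal()
}

#' Volcano-style view of differentially predicted genes
#'
#' @param result A result tibble with `p_value` and `mean_difference`
#'   columns ([wilcoxon_differential()]).
#' @param alpha Significance level drawn as a horizontal guide.
#' @return A ggplot of mean score difference vs -log10 p-value.
#' @export
plot_differential <- function(result, alpha = 0.05) {
  stopifnot(all(c("p_value", "mean_difference") %in% names(result)))
  ggplot(result, aes(x = .data$mean_difference,
                     y = -log10(.data$p_value))) +
    geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = "mean score difference (group A - group B)",
         y = expression(-log[10]~p)) +
    theme_minimal()
}

#' Per-channel distribution of combined gene scores
#'
#' @param channel_matrix Long score tibble from [build_channel_matrix()].
#' @return A ggplot (boxplots per channel, faceted by label).
#' @export
plot_channel_scores <- function(channel_matrix) {
  ggplot(channel_matrix, aes(x = .data$channel, y = .data$score)) +
    geom_boxplot(outlier.alpha = 0.3) +
    facet_wrap(~label) +
    labs(x = NULL, y = "combined per-gene score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
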