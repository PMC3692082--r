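#' Per-gene difference between two score columns
#'
#' @param result Wide result tibble (one score column per label).
#' @param label_a,label_b Column names to compare.
#' @return The result tibble with an added `difference` column,
#'   `score(label_a) - score(label_b)` per gene.
#' @export
score_difference <- function(result, label_a, label_b) {
  for (lab in c(label_a, label_b)) {
    if (!lab %in% names(result)) abort(paste0("unknown label '", lab, "'"))
  }
  mutate(result, difference = .data[[label_a]] - .data[[label_b]])
}

# Exact two-sided rank-sum p-value via the null Wilcoxon distribution
# (tie-free case only).
exact_wilcox_p <- function(xa, xb) {
  n <- length(xa); m <- length(xb)
  r <- rank(c(xa, xb))
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2      # Mann-Whitney U for group A
  lower <- pwilcox(w, n, m)
  upper <- 1 - pwilcox(w - 1, n, m)
  min(1, 2 * min(lower, upper))
}

# Exact two-sided p-value by enumerating all C(n+m, n) group assignments of
# the pooled midranks; handles ties.
enumerated_wilcox_p <- function(xa, xb) {
  n <- length(xa); m <- length(xb)
  r <- rank(c(xa, xb))                            # midranks
  w_obs <- sum(r[seq_len(n)])
  picks <- combn(n + m, n)
  w_all <- colSums(matrix(r[picks], nrow = n))
  center <- n * (n + m + 1) / 2
  # two-sided: assignments at least as extreme about the null center
  mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
}

# Two-sided rank-sum p for one gene: exact for small groups (enumeration
# when ties are present), normal approximation with continuity correction
# otherwise.
ranksum_p <- function(xa, xb) {
  ties <- anyDuplicated(c(xa, xb)) > 0L
  if (min(length(xa), length(xb)) <= 8L) {
    if (ties) enumerated_wilcox_p(xa, xb) else exact_wilcox_p(xa, xb)
  } else {
    suppressWarnings(
      wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value
    )
  }
}

#' Differentially predicted genes between two sample groups
#'
#' For each gene, a two-sided Wilcoxon rank-sum test compares its scores (or
#' its per-sample fractional ranks, with `use_ranks`) across the samples of
#' group A vs group B.  Genes with small p-values are "differentially
#' predicted": the same miRNA list, at the two groups' expression levels,
#' assigns them different targeting potential.  The null distribution is
#' exact for small groups (enumeration over all assignments when ties are
#' present) and a continuity-corrected normal approximation for larger
#' ones.  Raw p-values are reported; set `adjust` for an additional
#' Benjamini-Hochberg column.
#'
#' @param result Wide result tibble (gene id column(s) + one score column
#'   per sample label).
#' @param group_a,group_b Disjoint sets of at least 3 sample labels each.
#' @param use_ranks Compare per-sample fractional ranks of the scores
#'   instead of the scores themselves.
#' @param adjust Add a `p_adjusted` Benjamini-Hochberg column.
#' @param alpha Optional significance level; when given, a logical
#'   `differential` column flags genes with `p_value <= alpha`.
#' @return The result tibble with `p_value` and `mean_difference`
#'   (mean over group A minus mean over group B) columns appended.
#' @export
wilcoxon_differential <- function(result, group_a, group_b, use_ranks = FALSE,
                                  adjust = FALSE, alpha = NULL) {
  if (length(intersect(group_a, group_b)) > 0L) abort("groups must be disjoint")
  if (length(group_a) < 3L || length(group_b) < 3L) {
    abort("each group needs at least 3 sample labels")
  }
  for (lab in c(group_a, group_b)) {
    if (!lab %in% names(result)) abort(paste0("unknown sample label '", lab, "'"))
  }
  a <- as.matrix(result[, group_a, drop = FALSE])
  b <- as.matrix(result[, group_b, drop = FALSE])
  if (use_ranks) {
    a <- apply(a, 2, function(col) rank(col) / length(col))
    b <- apply(b, 2, function(col) rank(col) / length(col))
  }
  p <- vapply(seq_len(nrow(result)),
              function(i) ranksum_p(a[i, ], b[i, ]), numeric(1))
  out <- mutate(result,
                p_value = p,
                mean_difference = rowMeans(a) - rowMeans(b))
  if (adjust) out <- mutate(out, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
  if (!is.null(alpha)) out <- mutate(out, differential = .data$p_value <= alpha)
  out
}

#' Drop genes not predicted as targets by any miRNA set
#'
#' @param result Wide result tibble.
#' @param threshold Score threshold in [0, 1] above (or at) which a gene
#'   counts as a predicted target.
#' @param drop_nontargets Actually remove the genes (default `TRUE`); with
#'   `FALSE` the table is returned unchanged.
#' @param labels Score columns to consider (default: all numeric columns
#'   except appended statistics columns).
#' @return The filtered result tibble.
#' @export
filter_targets <- function(result, threshold, drop_nontargets = TRUE,
                           labels = NULL) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1]")
  if (!drop_nontargets || threshold == 0) return(result)
  if (is.null(labels)) {
    stat_cols <- c("difference", "p_value", "mean_difference", "p_adjusted",
                   "differential")
    labels <- setdiff(names(result)[vapply(result, is.numeric, logical(1))],
                      stat_cols)
  }
  mx <- do.call(pmax, result[, labels, drop = FALSE])
  result[mx >= threshold, , drop = FALSE]
}
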