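# Cross-platform differential expression: within-sample rank transform,
# Mann-Whitney testing, dual significance thresholds.

#' Filter genes with low average expression
#'
#' In the default `both_cohorts` mode a gene is removed only when its mean
#' normalized expression is below `threshold` in cohort 1 AND in cohort 2
#' (retained if adequately expressed in at least one); `pooled` mode uses
#' the pooled mean instead.
#'
#' @param expr Gene-by-sample matrix.
#' @param samples Sample tibble (`sample_id`, `cohort`) covering the matrix
#'   columns.
#' @param threshold Mean-expression cutoff (strict `<`, default 10).
#' @param mode `"both_cohorts"` or `"pooled"`.
#' @return Filtered gene-by-sample matrix.
#' @export
filter_low_expression <- function(expr, samples, threshold = 10,
                                  mode = c("both_cohorts", "pooled")) {
  mode <- match.arg(mode)
  cohorts <- cohort_pair(samples)
  if (mode == "pooled") {
    keep <- rowMeans(expr) >= threshold
  } else {
    m1 <- rowMeans(expr[, samples$sample_id[samples$cohort == cohorts[1]],
                        drop = FALSE])
    m2 <- rowMeans(expr[, samples$sample_id[samples$cohort == cohorts[2]],
                        drop = FALSE])
    keep <- m1 >= threshold | m2 >= threshold
  }
  expr[keep, , drop = FALSE]
}

#' Within-sample average-rank transform
#'
#' Replaces each sample's expression values by their ranks within the sample
#' (rank 1 = lowest; ties get the average rank), so downstream tests compare
#' relative rather than absolute expression — the device that makes the
#' comparison robust to platform-specific monotone distortions.
#'
#' @param expr Gene-by-sample matrix.
#' @return Matrix of the same shape holding per-sample average ranks.
#' @export
rank_transform <- function(expr) {
  apply(expr, 2, rank)
}

#' Rank-based differential expression between cohorts
#'
#' Per gene, a two-sided Mann-Whitney test on the rank-transformed rows
#' across cohorts with BH adjustment over the retained genes; the log2 fold
#' change is computed on the original normalized values
#' (`log2((mean_1 + pseudocount) / (mean_2 + pseudocount))`), since ranks
#' are platform-comparable but not scale-interpretable. A gene is a DEG when
#' `q < p_threshold` and `|log2FC| >= lfc_threshold`.
#'
#' @param ranks Rank matrix from [rank_transform()].
#' @param original The matching original expression matrix (same genes and
#'   samples).
#' @param samples Sample tibble.
#' @param p_threshold Adjusted-p cutoff (default 0.01).
#' @param lfc_threshold Absolute log2-fold-change cutoff (default 2).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @param cohort_order Optional cohort ordering (first = fold-change
#'   numerator).
#' @return Tibble of class `deg_results`: per gene `mean_1`, `mean_2`,
#'   `log2_fold_change`, `p`, `q`, `deg`, `direction` (`up_1`/`up_2`).
#' @export
test_differential_expression <- function(ranks, original, samples,
                                         p_threshold = 0.01,
                                         lfc_threshold = 2, pseudocount = 1,
                                         cohort_order = NULL) {
  if (!identical(rownames(ranks), rownames(original)) ||
      !identical(colnames(ranks), colnames(original))) {
    abort("ranks and original matrices must share genes and samples")
  }
  cohorts <- cohort_pair(samples, cohort_order)
  idx1 <- colnames(ranks) %in% samples$sample_id[samples$cohort == cohorts[1]]
  idx2 <- colnames(ranks) %in% samples$sample_id[samples$cohort == cohorts[2]]
  p <- vapply(seq_len(nrow(ranks)), function(i) {
    mann_whitney_u(ranks[i, idx1], ranks[i, idx2], mode = "normal")$p_value
  }, 0)
  m1 <- unname(rowMeans(original[, idx1, drop = FALSE]))
  m2 <- unname(rowMeans(original[, idx2, drop = FALSE]))
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  q <- bh_adjust(p)
  res <- tibble(
    gene = rownames(ranks), mean_1 = m1, mean_2 = m2,
    log2_fold_change = lfc, p = p, q = q,
    deg = q < p_threshold & abs(lfc) >= lfc_threshold,
    direction = ifelse(lfc > 0, "up_1", ifelse(lfc < 0, "up_2", NA_character_))
  ) |>
    arrange(.data$q, .data$p)
  structure(res, class = c("deg_results", class(res)), cohorts = cohorts,
            p_threshold = p_threshold, lfc_threshold = lfc_threshold)
}

#' Run the full expression-difference stage
#'
#' Convenience wrapper: low-expression filter, rank transform, and
#' differential test in one call.
#'
#' @inheritParams test_differential_expression
#' @inheritParams filter_low_expression
#' @param filter_mode Passed to [filter_low_expression()] as `mode`.
#' @return A `deg_results` tibble (see
#'   [test_differential_expression()]).
#' @export
run_expression_diff <- function(expr, samples, threshold = 10,
                                filter_mode = "both_cohorts",
                                p_threshold = 0.01, lfc_threshold = 2,
                                pseudocount = 1, cohort_order = NULL) {
  kept <- filter_low_expression(expr, samples, threshold, filter_mode)
  ranks <- rank_transform(kept)
  test_differential_expression(ranks, kept, samples, p_threshold,
                               lfc_threshold, pseudocount, cohort_order)
}
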