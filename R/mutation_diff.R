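# Gene-level mutation-frequency comparison between two cohorts.

#' Build a binary gene-by-sample mutation indicator
#'
#' Collapses filtered variants to a panel-gene by sample 0/1 matrix (1 =
#' the sample carries at least one retained variant in the gene). The full
#' sample roster must be supplied so unmutated samples appear as all-zero
#' columns.
#'
#' @param variants Filtered variant tibble.
#' @param samples Sample tibble (`sample_id`, `cohort`) covering every sample
#'   in both cohorts.
#' @param panel Character vector of panel genes (matrix rows).
#' @return An object of class `mutation_matrix`: list with `indicator`
#'   (genes x samples integer matrix) and `samples`.
#' @export
build_mutation_matrix <- function(variants, samples, panel) {
  stray <- setdiff(unique(variants$sample_id), samples$sample_id)
  if (length(stray) > 0) {
    abort(sprintf("variant sample(s) not on the roster: %s",
                  paste(stray, collapse = ", ")))
  }
  v <- filter(variants, .data$gene %in% panel)
  m <- matrix(0L, nrow = length(panel), ncol = nrow(samples),
              dimnames = list(panel, samples$sample_id))
  if (nrow(v) > 0) {
    hits <- distinct(v, .data$gene, .data$sample_id)
    m[cbind(match(hits$gene, panel), match(hits$sample_id, samples$sample_id))] <- 1L
  }
  structure(list(indicator = m, samples = as_tibble(samples)),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix> %d genes x %d samples (%s)\n",
              nrow(x$indicator), ncol(x$indicator),
              paste(sprintf("%s: %d", names(table(x$samples$cohort)),
                            table(x$samples$cohort)), collapse = ", ")))
  invisible(x)
}

# Fisher tests for many genes sharing the same margins; memoized on (a, c).
fisher_many <- function(a, c_, n1, n2) {
  key <- paste(a, c_, sep = "_")
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    fisher_p(a[i], n1 - a[i], c_[i], n2 - c_[i])
  }, 0)
  names(pu) <- key[uk]
  unname(pu[key])
}

#' Test per-gene mutation frequencies between cohorts
#'
#' One two-sided Fisher's exact test per panel gene on the 2x2 table
#' (mutated vs not, cohort 1 vs cohort 2), with Benjamini-Hochberg
#' adjustment. By default the BH family is the genes with at least one
#' mutated sample in the combined cohort; never-mutated genes are reported
#' with `tested = FALSE` and no q-value.
#'
#' @param mm A [build_mutation_matrix()] result.
#' @param fdr_threshold Significance cutoff on the adjusted p-value
#'   (default 0.1).
#' @param cohort_order Optional length-2 vector fixing which cohort is
#'   "cohort 1" (the odds-ratio numerator); default alphabetical.
#' @param universe `"mutated"` (default) restricts the BH family to genes
#'   mutated at least once; `"all"` adjusts across every panel gene.
#' @return Tibble of class `gene_mutation_tests`: one row per panel gene with
#'   counts, frequencies, `odds_ratio`, `p`, `q`, `significant`,
#'   `enriched_cohort`, `tested`.
#' @export
test_gene_frequencies <- function(mm, fdr_threshold = 0.1,
                                  cohort_order = NULL,
                                  universe = c("mutated", "all")) {
  universe <- match.arg(universe)
  cohorts <- cohort_pair(mm$samples, cohort_order)
  s1 <- mm$samples$sample_id[mm$samples$cohort == cohorts[1]]
  s2 <- mm$samples$sample_id[mm$samples$cohort == cohorts[2]]
  if (length(s1) == 0 || length(s2) == 0) abort("both cohorts must be non-empty")
  m <- mm$indicator
  a <- unname(rowSums(m[, s1, drop = FALSE]))
  c_ <- unname(rowSums(m[, s2, drop = FALSE]))
  n1 <- length(s1); n2 <- length(s2)
  res <- tibble(
    gene = rownames(m),
    n_mut_1 = as.integer(a), n_1 = n1,
    n_mut_2 = as.integer(c_), n_2 = n2,
    freq_1 = a / n1, freq_2 = c_ / n2,
    odds_ratio = ifelse((n1 - a) * c_ == 0,
                        ifelse(a * (n2 - c_) == 0, NA_real_, Inf),
                        (a * (n2 - c_)) / ((n1 - a) * c_)),
    tested = (a + c_) > 0 | universe == "all"
  )
  res$p <- NA_real_
  res$p[res$tested] <- fisher_many(a[res$tested], c_[res$tested], n1, n2)
  res$q <- NA_real_
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res$significant <- !is.na(res$q) & res$q < fdr_threshold
  res$enriched_cohort <- ifelse(res$freq_1 > res$freq_2, cohorts[1],
                                ifelse(res$freq_2 > res$freq_1, cohorts[2],
                                       NA_character_))
  res <- arrange(res, .data$p)
  structure(res, class = c("gene_mutation_tests", class(res)),
            cohorts = cohorts, fdr_threshold = fdr_threshold)
}

#' Bootstrap stability of a gene's log odds ratio
#'
#' Resamples samples with replacement independently within each cohort
#' (preserving cohort sizes), recomputes the log odds ratio per resample,
#' and reports the spread and directional consistency (fraction of
#' resamples whose log-OR sign matches the point estimate; when the point
#' estimate is exactly zero there is no direction to agree with, and the
#' positive-sign fraction — near 0.5 under a null — is reported instead).
#' Haldane-Anscombe
#' smoothing (+0.5 on all four cells) is applied to a table only when it
#' contains a zero cell, so well-populated tables are untouched.
#'
#' @param mm A [build_mutation_matrix()] result.
#' @param gene Gene symbol present in the matrix.
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param seed Integer seed; identical seeds give identical output.
#' @param cohort_order Optional cohort ordering, as in
#'   [test_gene_frequencies()].
#' @return One-row tibble: `gene`, `n_resamples`, `log_or` (point estimate),
#'   `boot_mean`, `boot_sd`, `consistency`.
#' @export
bootstrap_log_or <- function(mm, gene, n_resamples = 5000, seed = 1L,
                             cohort_order = NULL) {
  if (n_resamples < 1) abort("n_resamples must be >= 1")
  if (!gene %in% rownames(mm$indicator)) {
    abort(sprintf("gene '%s' not in the mutation matrix", gene))
  }
  cohorts <- cohort_pair(mm$samples, cohort_order)
  x1 <- mm$indicator[gene, mm$samples$sample_id[mm$samples$cohort == cohorts[1]]]
  x2 <- mm$indicator[gene, mm$samples$sample_id[mm$samples$cohort == cohorts[2]]]
  n1 <- length(x1); n2 <- length(x2)
  log_or_cells <- function(a, c_) {
    b <- n1 - a; d <- n2 - c_
    if (any(c(a, b, c_, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    log((a * d) / (b * c_))
  }
  point <- log_or_cells(sum(x1), sum(x2))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  boots <- withr_seed({
    # resampling a binary column vector with replacement == binomial draw on
    # the empirical mutation rate
    a_star <- rbinom(n_resamples, n1, mean(x1))
    c_star <- rbinom(n_resamples, n2, mean(x2))
    vapply(seq_len(n_resamples),
           function(i) log_or_cells(a_star[i], c_star[i]), 0)
  })
  consistency <- if (point == 0) {
    # no direction to agree with: report the positive-sign fraction, which
    # straddles 0.5 under a null effect
    mean(boots >= 0)
  } else {
    mean(sign(boots) == sign(point))
  }
  tibble(
    gene = gene, n_resamples = as.integer(n_resamples),
    log_or = point, boot_mean = mean(boots), boot_sd = sd(boots),
    consistency = consistency
  )
}

#' Deterministic oncoplot-style mutation table
#'
#' Gene-by-sample classification labels; multiple hits in one gene/sample
#' are joined with `";"` in a sorted, deterministic order. A tabular stand-in
#' for an oncoplot.
#'
#' @param variants Filtered variant tibble.
#' @param samples Sample roster tibble.
#' @param panel Panel gene vector (row universe and order).
#' @return Long tibble `gene`, `sample_id`, `cohort`, `classes` ("" when
#'   unmutated), sorted by gene then sample.
#' @export
oncotable <- function(variants, samples, panel) {
  hits <- variants |>
    filter(.data$gene %in% panel) |>
    group_by(.data$gene, .data$sample_id) |>
    summarise(classes = paste(sort(.data$classification), collapse = ";"),
              .groups = "drop")
  tidyr::expand_grid(gene = panel, sample_id = samples$sample_id) |>
    left_join(samples, by = "sample_id") |>
    left_join(hits, by = c("gene", "sample_id")) |>
    mutate(classes = ifelse(is.na(.data$classes), "", .data$classes)) |>
    arrange(.data$gene, .data$sample_id)
}
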