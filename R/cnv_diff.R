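# Copy-number comparison: segment-to-gene status assignment with conflict
# invalidation, per-gene frequency tests, chromosome-arm aggregation, and
# per-sample burden.

gene_status_levels <- c("gain", "loss", "neutral", "invalid", "missing")

#' Assign per-gene CNV status from segment calls
#'
#' For each sample and panel gene, collects the states of all segments
#' overlapping the gene (0-based half-open intersection, at least 1 bp) and
#' resolves them to one status. In the default `gain_loss_only` mode a gene
#' is `invalid` only when both a gain and a loss overlap it; an alteration
#' co-occurring with neutral segments resolves to the alteration. In
#' `strict` mode any two distinct overlapping states invalidate the gene.
#' Genes with no overlapping segment are `missing`.
#'
#' @param segments Segment tibble (see [read_seg()]).
#' @param genes Panel gene coordinates (see [read_bed_panel()]).
#' @param samples Sample roster tibble (`sample_id`, `cohort`); samples with
#'   no segments get all-missing genes.
#' @param conflict_mode `"gain_loss_only"` (default) or `"strict"`.
#' @return Long tibble `sample_id`, `gene`, `status` covering the full
#'   roster-by-panel grid.
#' @export
assign_gene_status <- function(segments, genes, samples,
                               conflict_mode = c("gain_loss_only", "strict")) {
  conflict_mode <- match.arg(conflict_mode)
  ov <- segments |>
    filter(.data$sample_id %in% samples$sample_id) |>
    inner_join(genes, by = "chromosome", suffix = c("_seg", "_gene"),
               relationship = "many-to-many") |>
    filter(.data$start_seg < .data$end_gene, .data$start_gene < .data$end_seg)
  resolved <- ov |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(has_gain = any(.data$state == "gain"),
              has_loss = any(.data$state == "loss"),
              n_states = dplyr::n_distinct(.data$state), .groups = "drop") |>
    mutate(status = dplyr::case_when(
      conflict_mode == "strict" & .data$n_states > 1 ~ "invalid",
      .data$has_gain & .data$has_loss ~ "invalid",
      .data$has_gain ~ "gain",
      .data$has_loss ~ "loss",
      TRUE ~ "neutral"
    )) |>
    select("sample_id", "gene", "status")
  tidyr::expand_grid(sample_id = samples$sample_id, gene = genes$gene) |>
    left_join(resolved, by = c("sample_id", "gene")) |>
    mutate(status = ifelse(is.na(.data$status), "missing", .data$status))
}

#' Complete a pre-called gene-level CNV table to the full grid
#'
#' The cohort observed at gene level (rather than segment level) enters the
#' same representation as segment-derived calls: panel genes absent from the
#' input for a sample become `missing`.
#'
#' @param status_df Tibble `sample_id`, `gene`, `status`
#'   (gain/loss/neutral).
#' @param genes Panel gene coordinates (only `gene` is used).
#' @param samples Sample roster tibble.
#' @return Long tibble `sample_id`, `gene`, `status` on the full grid.
#' @export
as_gene_cnv <- function(status_df, genes, samples) {
  bad <- setdiff(unique(status_df$status), gene_status_levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown CNV status: %s", paste(bad, collapse = ", ")))
  }
  tidyr::expand_grid(sample_id = samples$sample_id, gene = genes$gene) |>
    left_join(status_df[, c("sample_id", "gene", "status")],
              by = c("sample_id", "gene")) |>
    mutate(status = ifelse(is.na(.data$status), "missing", .data$status))
}

#' Test per-gene CNV event frequencies between cohorts
#'
#' For one event type (`gain`, `loss`, or `change` = gain or loss), builds a
#' 2x2 table per gene of event vs valid-non-event by cohort and applies
#' Fisher's exact test with BH adjustment. Denominators count only samples
#' with a valid status (gain/loss/neutral) for that gene; `invalid` and
#' `missing` samples are excluded. Genes with no valid sample in either
#' cohort are skipped (`tested = FALSE` with a reason).
#'
#' @param gene_cnv Long status tibble on the full grid.
#' @param samples Sample roster tibble.
#' @param event `"gain"`, `"loss"`, or `"change"`.
#' @param fdr_threshold Adjusted-p cutoff (default 0.05).
#' @param cohort_order Optional cohort ordering (first = OR numerator).
#' @return Tibble of class `gene_cnv_tests`: per gene, valid counts and
#'   event counts per cohort, frequencies, `odds_ratio`, `log2_odds_ratio`
#'   with an `or_infinite` flag, `p`, `q`, `significant`, `enriched_cohort`.
#' @export
test_cnv_frequencies <- function(gene_cnv, samples,
                                 event = c("gain", "loss", "change"),
                                 fdr_threshold = 0.05, cohort_order = NULL) {
  event <- match.arg(event)
  cohorts <- cohort_pair(samples, cohort_order)
  is_event <- function(st) {
    if (event == "change") st %in% c("gain", "loss") else st == event
  }
  tab <- gene_cnv |>
    left_join(samples, by = "sample_id") |>
    group_by(.data$gene, .data$cohort) |>
    summarise(valid = sum(.data$status %in% c("gain", "loss", "neutral")),
              events = sum(is_event(.data$status)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cohort",
                       values_from = c("valid", "events"))
  v1 <- tab[[paste0("valid_", cohorts[1])]]
  v2 <- tab[[paste0("valid_", cohorts[2])]]
  e1 <- tab[[paste0("events_", cohorts[1])]]
  e2 <- tab[[paste0("events_", cohorts[2])]]
  res <- tibble(
    gene = tab$gene, event = event,
    n_event_1 = e1, n_valid_1 = v1, n_event_2 = e2, n_valid_2 = v2,
    freq_1 = ifelse(v1 > 0, e1 / v1, NA_real_),
    freq_2 = ifelse(v2 > 0, e2 / v2, NA_real_),
    tested = v1 > 0 & v2 > 0,
    skip_reason = ifelse(v1 > 0 & v2 > 0, NA_character_,
                         "no valid sample in one cohort")
  )
  or <- ifelse((v1 - e1) * e2 == 0,
               ifelse(e1 * (v2 - e2) == 0, NA_real_, Inf),
               (e1 * (v2 - e2)) / ((v1 - e1) * e2))
  res$odds_ratio <- or
  res$or_infinite <- is.infinite(or) | (!is.na(or) & or == 0)
  res$log2_odds_ratio <- suppressWarnings(log2(or))
  res$p <- NA_real_
  idx <- which(res$tested)
  res$p[idx] <- vapply(idx, function(i) {
    # degenerate margins (no events anywhere, or events everywhere) carry
    # no information: p = 1 without invoking the test
    if (e1[i] + e2[i] == 0 || (v1[i] - e1[i]) + (v2[i] - e2[i]) == 0) {
      return(1)
    }
    fisher_exact_two_sided(e1[i], v1[i] - e1[i], e2[i], v2[i] - e2[i])$p_value
  }, 0)
  res$q <- NA_real_
  res$q[idx] <- bh_adjust(res$p[idx])
  res$significant <- !is.na(res$q) & res$q < fdr_threshold
  res$enriched_cohort <- ifelse(!res$tested, NA_character_,
                                ifelse(res$freq_1 > res$freq_2, cohorts[1],
                                       ifelse(res$freq_2 > res$freq_1,
                                              cohorts[2], NA_character_)))
  res <- arrange(res, .data$p)
  structure(res, class = c("gene_cnv_tests", class(res)),
            cohorts = cohorts, fdr_threshold = fdr_threshold)
}

#' Collapse gene-level CNV statuses to chromosome arms
#'
#' A sample's arm carries a gain (loss) flag if at least one panel gene
#' assigned to that arm has status gain (loss) in the sample. Genes are
#' assigned to the arm containing their midpoint; genes whose midpoint falls
#' outside every arm interval are left unassigned with a warning.
#'
#' @param gene_cnv Long status tibble on the full grid.
#' @param genes Panel gene coordinates.
#' @param arms Arm intervals (see [read_cytoband_arms()]).
#' @return Object of class `arm_cnv_table`: list with `flags` (tibble
#'   `sample_id`, `arm_label`, `gained`, `lost`) and `burden` (tibble
#'   `sample_id`, `n_arms_gained`, `n_arms_lost`).
#' @export
collapse_to_arms <- function(gene_cnv, genes, arms) {
  g <- genes |>
    mutate(midpoint = floor((.data$start + .data$end) / 2)) |>
    left_join(arms, by = "chromosome", suffix = c("", "_arm"),
              relationship = "many-to-many") |>
    filter(!is.na(.data$arm), .data$midpoint >= .data$start_arm,
           .data$midpoint < .data$end_arm) |>
    select("gene", "arm_label")
  unassigned <- setdiff(genes$gene, g$gene)
  if (length(unassigned) > 0) {
    warn(sprintf("%d gene(s) with midpoint outside all arm intervals left unassigned",
                 length(unassigned)))
  }
  flags <- gene_cnv |>
    inner_join(g, by = "gene", relationship = "many-to-many") |>
    group_by(.data$sample_id, .data$arm_label) |>
    summarise(gained = any(.data$status == "gain"),
              lost = any(.data$status == "loss"), .groups = "drop")
  burden <- flags |>
    group_by(.data$sample_id) |>
    summarise(n_arms_gained = sum(.data$gained), n_arms_lost = sum(.data$lost),
              .groups = "drop")
  structure(list(flags = flags, burden = burden), class = "arm_cnv_table")
}

#' Test per-arm CNV event frequencies between cohorts
#'
#' Per arm and event type (gain, loss), a 2x2 Fisher's exact test of flagged
#' vs unflagged samples by cohort; BH adjustment across arms separately
#' within each event type.
#'
#' @param arm_table An [collapse_to_arms()] result.
#' @param samples Sample roster tibble.
#' @param fdr_threshold Adjusted-p cutoff (default 0.05).
#' @param cohort_order Optional cohort ordering.
#' @return Tibble: `arm_label`, `event`, counts, frequencies, `odds_ratio`,
#'   `p`, `q`, `significant`, `enriched_cohort`.
#' @export
test_arm_frequencies <- function(arm_table, samples, fdr_threshold = 0.05,
                                 cohort_order = NULL) {
  cohorts <- cohort_pair(samples, cohort_order)
  flags <- arm_table$flags |>
    left_join(samples, by = "sample_id")
  n1 <- sum(samples$cohort == cohorts[1])
  n2 <- sum(samples$cohort == cohorts[2])
  per_event <- function(col, event) {
    counts <- flags |>
      group_by(.data$arm_label) |>
      summarise(a = sum(.data[[col]] & .data$cohort == cohorts[1]),
                c_ = sum(.data[[col]] & .data$cohort == cohorts[2]),
                .groups = "drop")
    res <- tibble(
      arm_label = counts$arm_label, event = event,
      n_event_1 = counts$a, n_1 = n1, n_event_2 = counts$c_, n_2 = n2,
      freq_1 = counts$a / n1, freq_2 = counts$c_ / n2,
      odds_ratio = ifelse((n1 - counts$a) * counts$c_ == 0,
                          ifelse(counts$a * (n2 - counts$c_) == 0, NA_real_, Inf),
                          (counts$a * (n2 - counts$c_)) /
                            ((n1 - counts$a) * counts$c_)),
      p = vapply(seq_len(nrow(counts)), function(i) {
        a <- counts$a[i]; c_ <- counts$c_[i]
        if (a + c_ == 0 || (n1 - a) + (n2 - c_) == 0) return(1)
        fisher_exact_two_sided(a, n1 - a, c_, n2 - c_)$p_value
      }, 0)
    )
    res$q <- bh_adjust(res$p)
    res$significant <- res$q < fdr_threshold
    res$enriched_cohort <- ifelse(res$freq_1 > res$freq_2, cohorts[1],
                                  ifelse(res$freq_2 > res$freq_1, cohorts[2],
                                         NA_character_))
    res
  }
  out <- bind_rows(per_event("gained", "gain"), per_event("lost", "loss")) |>
    arrange(.data$event, .data$p)
  structure(out, class = c("arm_cnv_tests", class(out)), cohorts = cohorts)
}

#' Compare per-sample chromosome-arm CNV burden between cohorts
#'
#' Burden is the number of arms per sample flagged with the event; the
#' comparison reports per-cohort means and a two-sided Wilcoxon rank-sum
#' p-value for gains and losses separately.
#'
#' @param arm_table An [collapse_to_arms()] result.
#' @param samples Sample roster tibble.
#' @param cohort_order Optional cohort ordering.
#' @return Tibble: `event`, `mean_1`, `mean_2`, `p`.
#' @export
compare_burden <- function(arm_table, samples, cohort_order = NULL) {
  cohorts <- cohort_pair(samples, cohort_order)
  b <- samples |>
    left_join(arm_table$burden, by = "sample_id") |>
    mutate(across(c("n_arms_gained", "n_arms_lost"),
                  ~ ifelse(is.na(.x), 0L, .x)))
  one <- function(col, event) {
    x <- b[[col]][b$cohort == cohorts[1]]
    y <- b[[col]][b$cohort == cohorts[2]]
    tibble(event = event, mean_1 = mean(x), mean_2 = mean(y),
           p = wilcoxon_rank_sum(x, y)$p_value)
  }
  bind_rows(one("n_arms_gained", "gain"), one("n_arms_lost", "loss"))
}
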