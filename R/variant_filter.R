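# Somatic-variant filtering cascade: population allele frequency ->
# protein-altering consequence -> panel restriction.

protein_altering_classes <- c(
  "missense", "nonsense", "frameshift_ins", "frameshift_del",
  "inframe_ins", "inframe_del", "splice_site", "translation_start_site"
)

#' Remove likely-germline variants by population allele frequency
#'
#' Drops variants whose population-maximum allele frequency is strictly
#' greater than `threshold`. Variants with no AF annotation are retained:
#' absence of evidence of commonness is not treated as commonness.
#'
#' @param variants Variant tibble (see [read_maf()]).
#' @param threshold AF cutoff as a fraction; default 5e-4.
#' @return Filtered variant tibble.
#' @export
filter_population_af <- function(variants, threshold = 0.0005) {
  if (threshold < 0) abort("threshold must be non-negative")
  filter(variants, is.na(.data$popmax_af) | .data$popmax_af <= threshold)
}

#' Keep only protein-altering variants
#'
#' Retains missense, nonsense, frameshift and in-frame insertions/deletions,
#' splice-site, and translation-start-site changes; silent, UTR, intronic,
#' flanking, and other non-coding classes are removed.
#'
#' @param variants Variant tibble.
#' @return Filtered variant tibble.
#' @export
filter_protein_altering <- function(variants) {
  filter(variants, .data$classification %in% protein_altering_classes)
}

#' Restrict variants to a gene panel
#'
#' @param variants Variant tibble.
#' @param panel Character vector of panel gene symbols (non-empty).
#' @return Filtered variant tibble.
#' @export
filter_panel <- function(variants, panel) {
  if (length(panel) == 0) abort("panel must be non-empty")
  filter(variants, .data$gene %in% panel)
}

#' Run the full variant-filter cascade
#'
#' Applies the three filters in order (population AF, protein-altering,
#' panel) and reports per-stage attrition. The final retained set is
#' order-invariant (the filters commute); only the per-stage counts depend
#' on the order.
#'
#' @param variants Variant tibble.
#' @param panel Character vector of panel genes.
#' @param af_threshold Population-AF cutoff.
#' @return List with `variants` (retained tibble) and `report`, a tibble of
#'   per-stage counts (`stage`, `removed`, `remaining`) whose removals sum
#'   to `input - retained`.
#' @export
run_filter_cascade <- function(variants, panel, af_threshold = 0.0005) {
  n0 <- nrow(variants)
  v1 <- filter_population_af(variants, af_threshold)
  v2 <- filter_protein_altering(v1)
  v3 <- filter_panel(v2, panel)
  report <- tibble(
    stage = c("input", "population_af", "non_protein_altering", "off_panel",
              "retained"),
    removed = c(0L, n0 - nrow(v1), nrow(v1) - nrow(v2), nrow(v2) - nrow(v3), 0L),
    remaining = c(n0, nrow(v1), nrow(v2), nrow(v3), nrow(v3))
  )
  list(variants = v3, report = report)
}
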