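# Hypergeometric over-representation analysis and the integrative
# multi-layer enrichment matrix.

#' Over-representation analysis of a gene set against a collection
#'
#' For each pathway in the collection, tests whether the query set overlaps
#' it more than expected by chance in the given universe, using the
#' hypergeometric upper tail. Query genes outside the universe are dropped
#' with a warning; pathways are intersected with the universe, and only
#' pathways with at least one universe gene enter the BH family.
#'
#' @param query Character vector of query genes.
#' @param collection Named list of pathway gene vectors (see [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @return Tibble of class `ora_results`, sorted by `q`: per pathway `N`,
#'   `K`, `n`, `k`, `overlap_genes` (list column), `p`, `q`, `significant`
#'   (q < 0.05).
#' @export
run_ora <- function(query, collection, universe) {
  if (length(universe) == 0 || length(query) == 0) {
    abort("query and universe must be non-empty")
  }
  universe <- unique(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped",
                 length(dropped)))
  }
  query <- intersect(unique(query), universe)
  if (length(query) == 0) abort("no query genes remain inside the universe")
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map_dfr(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    K <- length(pw)
    if (K == 0) return(NULL)
    ov <- intersect(query, pw)
    k <- length(ov)
    tibble(pathway = nm, N = N, K = K, n = n, k = k,
           overlap_genes = list(sort(ov)),
           p = hypergeom_upper_tail(N, K, n, k))
  })
  if (nrow(rows) == 0) abort("no pathway overlaps the universe")
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < 0.05
  rows <- arrange(rows, .data$q, .data$p, .data$pathway)
  structure(rows, class = c("ora_results", class(rows)))
}

#' Assemble the integrative multi-layer enrichment matrix
#'
#' Combines per-layer ORA results (e.g. the seven layers: differentially
#' mutated genes, up-regulated DEGs per cohort, and CNV gain/loss gene sets
#' per cohort) into a pathway-by-layer matrix of `-log10(q)`. Cells where a
#' layer has zero overlap with the pathway are empty (`NA`), not 0; stars
#' mark `q < 0.05`. Rows are ordered by the number of layers with
#' significant enrichment (descending), ties alphabetical by pathway.
#'
#' @param layer_results Named list of `ora_results` tibbles; names are the
#'   layer labels (must be unique).
#' @return Object of class `integrative_matrix`: list with `long` (tibble
#'   `pathway`, `layer`, `neglog10_q`, `significant`, `k`) and `matrix`
#'   (wide tibble, one column per layer, rows in rank order, plus
#'   `n_significant_layers`).
#' @export
build_integrative_matrix <- function(layer_results) {
  if (is.null(names(layer_results)) || anyDuplicated(names(layer_results))) {
    abort("layer_results must have unique names")
  }
  long <- purrr::imap_dfr(layer_results, function(res, nm) {
    tibble(pathway = res$pathway, layer = nm, k = res$k, q = res$q,
           neglog10_q = ifelse(res$k == 0, NA_real_, -log10(res$q)),
           significant = res$k > 0 & res$significant)
  })
  rank_tbl <- long |>
    group_by(.data$pathway) |>
    summarise(n_significant_layers = sum(.data$significant), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_significant_layers), .data$pathway)
  wide <- long |>
    mutate(cell = ifelse(is.na(.data$neglog10_q), NA_real_, .data$neglog10_q)) |>
    select("pathway", "layer", "cell") |>
    tidyr::pivot_wider(names_from = "layer", values_from = "cell") |>
    left_join(rank_tbl, by = "pathway") |>
    arrange(dplyr::desc(.data$n_significant_layers), .data$pathway)
  structure(list(long = long, matrix = wide), class = "integrative_matrix")
}

#' @export
print.integrative_matrix <- function(x, ...) {
  cat(sprintf("<integrative_matrix> %d pathways x %d layers\n",
              nrow(x$matrix), length(unique(x$long$layer))))
  print(x$matrix, n = 10)
  invisible(x)
}
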