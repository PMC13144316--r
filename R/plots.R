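# ggplot2 views of each result type. These are presentation-only; the
# underlying tibbles keep exact counts (infinite odds ratios are truncated
# to the plot limits, as is conventional for CNV volcano plots).

#' Volcano-style plot of gene mutation tests
#'
#' Frequency difference (cohort 1 minus cohort 2) against `-log10(q)`.
#'
#' @param object A `gene_mutation_tests` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_mutation_tests <- function(object, ...) {
  fdr <- attr(object, "fdr_threshold") %||% 0.1
  df <- filter(as_tibble(object), .data$tested)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q),
                                   y = .data$freq_1 - .data$freq_2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey50")) +
    ggplot2::geom_vline(xintercept = -log10(fdr), linetype = 2) +
    ggplot2::labs(x = "-log10(FDR)", y = "frequency difference (1 - 2)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of CNV gene tests
#'
#' `log2(odds ratio)` against `-log10(q)`; infinite or zero odds ratios are
#' truncated to the finite plot limits.
#'
#' @param object A `gene_cnv_tests` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_cnv_tests <- function(object, ...) {
  df <- filter(as_tibble(object), .data$tested)
  finite <- df$log2_odds_ratio[is.finite(df$log2_odds_ratio)]
  lim <- if (length(finite) > 0) max(abs(finite), 1) else 1
  df$lor <- pmax(pmin(df$log2_odds_ratio, lim), -lim)
  df$lor[is.na(df$lor)] <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lor, y = -log10(.data$q))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey50")) +
    ggplot2::labs(x = "log2(odds ratio), truncated", y = "-log10(FDR)",
                  title = unique(df$event)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression results
#'
#' @param object A `deg_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_results <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = -log10(.data$q))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$deg), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "log2 fold change (1 over 2)",
                  y = "-log10(adjusted p)") +
    ggplot2::theme_minimal()
}

#' Spectrum plot of extracted signatures
#'
#' One facet per signature, bars over the 96 substitution classes.
#'
#' @param object A `signature_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_model <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$W), rownames = "type") |>
    tidyr::pivot_longer(-"type", names_to = "signature",
                        values_to = "probability") |>
    mutate(type = factor(.data$type, levels = sbs96_types()),
           class = substr(as.character(.data$type), 3, 5))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$probability,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~signature, ncol = 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "SBS96 class", y = "probability")
}

#' Heatmap of the integrative enrichment matrix
#'
#' Tiles of `-log10(q)` per pathway and layer; empty (no-overlap) cells stay
#' blank, stars mark significant enrichment; rows keep the
#' count-then-alphabetical ranking.
#'
#' @param object An `integrative_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.integrative_matrix <- function(object, ...) {
  ord <- rev(object$matrix$pathway)
  df <- object$long |>
    mutate(pathway = factor(.data$pathway, levels = ord),
           star = ifelse(.data$significant, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$pathway,
                                   fill = .data$neglog10_q)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star)) +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "red",
                                 na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10(q)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
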