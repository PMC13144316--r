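# SBS96 classification helpers: six pyrimidine-centered substitution classes
# crossed with 16 flanking-base contexts.

sbs96_subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
dna_bases <- c("A", "C", "G", "T")

#' Canonical SBS96 mutation-type labels
#'
#' Returns the 96 single-base-substitution class labels in the COSMIC
#' convention: substitution classes `C>A, C>G, C>T, T>A, T>C, T>G` in that
#' order, each crossed with the 16 flanking-base contexts in alphabetical
#' order, e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_types <- function() {
  unlist(lapply(sbs96_subs, function(s) {
    as.vector(t(outer(dna_bases, dna_bases,
                      function(p, q) paste0(p, "[", s, "]", q))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), ""))
}

# Map (ref, alt, trinucleotide context) to an SBS96 class label, reverse
# complementing purine-reference substitutions. Returns NA for non-ACGT input.
sbs96_class <- function(ref, alt, context) {
  ok <- ref %in% dna_bases & alt %in% dna_bases & ref != alt &
    nchar(context) == 3 & !is.na(context) &
    !grepl("[^ACGT]", context)
  out <- rep(NA_character_, length(ref))
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pur <- r %in% c("A", "G")
  r[pur] <- chartr("ACGT", "TGCA", r[pur])
  a[pur] <- chartr("ACGT", "TGCA", a[pur])
  ctx[pur] <- revcomp(ctx[pur])
  out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  out
}
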