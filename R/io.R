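# Readers and writers for every external format the pipeline touches.
# Convention after ingestion: all genomic intervals (genes, segments, arms)
# are 0-based half-open; MAF point positions stay 1-based as in the format.
# Chromosome names are stored without a "chr" prefix.

cnv_states <- c("gain", "loss", "neutral")

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

normalize_chromosome <- function(chrom) {
  sub("^chr", "", chrom)
}

drop_nonstandard_contigs <- function(df, quiet = FALSE) {
  keep <- df$chromosome %in% c(as.character(1:22), "X", "Y")
  n_drop <- sum(!keep)
  if (n_drop > 0 && !quiet) {
    inform(sprintf("dropped %d record(s) on mitochondrial/alt contigs", n_drop))
  }
  df[keep, , drop = FALSE]
}

variant_class_map <- function() {
  path <- system.file("extdata", "variant_class_map.tsv", package = "stratomics")
  map <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  setNames(map$classification, map$maf_term)
}

#' Read somatic variants from a MAF file
#'
#' Parses a tab-delimited Mutation Annotation Format file into a variant
#' tibble. Variant classifications are mapped to a controlled vocabulary via
#' a packaged mapping table (unknown terms map to `"other"`); the
#' population-maximum allele frequency `popmax_af` is the row-wise maximum
#' over the configured allele-frequency columns, mirroring "common in any
#' subpopulation" semantics.
#'
#' @param path MAF file path. Lines starting with `#` are comments.
#' @param af_columns Character vector of allele-frequency column names to
#'   maximize over; `NULL` auto-detects columns matching `^gnomAD.*AF`.
#' @param context_column Optional column holding the reference-strand
#'   trinucleotide context of each variant.
#' @return Tibble with columns `sample_id`, `gene`, `classification`,
#'   `chromosome`, `position` (1-based), `ref`, `alt`, `popmax_af`, `context`.
#' @export
read_maf <- function(path, af_columns = NULL,
                     context_column = "Trinucleotide_Context") {
  df <- read_tsv_quiet(path, comment = "#",
                       col_types = readr::cols(.default = "c"))
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
           "Chromosome", "Start_Position", "Reference_Allele",
           "Tumor_Seq_Allele2")
  require_columns(df, req, "MAF file")
  if (nrow(df) == 0) return(empty_variants())
  pos <- suppressWarnings(as.numeric(df$Start_Position))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("unparsable Start_Position at data row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (is.null(af_columns)) {
    af_columns <- grep("^gnomAD.*AF", names(df), value = TRUE)
  }
  af_columns <- intersect(af_columns, names(df))
  popmax <- if (length(af_columns) == 0) {
    rep(NA_real_, nrow(df))
  } else {
    af <- vapply(af_columns,
                 function(cl) suppressWarnings(as.numeric(df[[cl]])),
                 numeric(nrow(df)))
    af <- matrix(af, nrow = nrow(df))
    apply(af, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  }
  map <- variant_class_map()
  cls <- unname(map[df$Variant_Classification])
  cls[is.na(cls)] <- "other"
  ctx <- if (context_column %in% names(df)) df[[context_column]] else NA_character_
  out <- tibble(
    sample_id = df$Tumor_Sample_Barcode,
    gene = df$Hugo_Symbol,
    classification = cls,
    chromosome = normalize_chromosome(df$Chromosome),
    position = pos,
    ref = df$Reference_Allele,
    alt = df$Tumor_Seq_Allele2,
    popmax_af = popmax,
    context = as.character(ctx)
  )
  drop_nonstandard_contigs(out)
}

empty_variants <- function() {
  tibble(sample_id = character(), gene = character(),
         classification = character(), chromosome = character(),
         position = numeric(), ref = character(), alt = character(),
         popmax_af = numeric(), context = character())
}

#' Write variants back to a MAF file
#'
#' Emits the controlled-vocabulary classification labels (which the reader
#' accepts unchanged), `popmax_af` as a `gnomAD_AF` column, and the context
#' column, so a write-then-read round trip reproduces the tibble.
#'
#' @param variants Variant tibble as returned by [read_maf()].
#' @param path Output path.
#' @export
write_maf <- function(variants, path) {
  out <- tibble(
    Hugo_Symbol = variants$gene,
    Tumor_Sample_Barcode = variants$sample_id,
    Variant_Classification = variants$classification,
    Chromosome = variants$chromosome,
    Start_Position = variants$position,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    gnomAD_AF = variants$popmax_af,
    Trinucleotide_Context = variants$context
  )
  out <- arrange(out, .data$Tumor_Sample_Barcode, .data$Chromosome,
                 .data$Start_Position, .data$Hugo_Symbol)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read segment-level copy-number calls
#'
#' @param path Tab-delimited file with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `state`.
#' @param coords Coordinate convention of the input: `"zero_based"`
#'   (half-open, kept as is) or `"one_based"` (inclusive, converted).
#' @return Tibble of segments in 0-based half-open coordinates with `state`
#'   in `gain`/`loss`/`neutral`.
#' @export
read_seg <- function(path, coords = c("zero_based", "one_based")) {
  coords <- match.arg(coords)
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("sample_id", "chromosome", "start", "end", "state"),
                  "SEG file")
  if (nrow(df) == 0) {
    return(tibble(sample_id = character(), chromosome = character(),
                  start = numeric(), end = numeric(), state = character()))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(start) || anyNA(end)) abort("unparsable segment coordinates")
  if (coords == "one_based") start <- start - 1
  bad_state <- !df$state %in% cnv_states
  if (any(bad_state)) {
    abort(sprintf("invalid CNV state '%s' at row %d; permitted states: %s",
                  df$state[which(bad_state)[1]], which(bad_state)[1],
                  paste(cnv_states, collapse = ", ")))
  }
  bad_iv <- start >= end
  if (any(bad_iv)) {
    abort(sprintf("segment with start >= end after normalization at row %d",
                  which(bad_iv)[1]))
  }
  out <- tibble(sample_id = df$sample_id,
                chromosome = normalize_chromosome(df$chromosome),
                start = start, end = end, state = df$state)
  drop_nonstandard_contigs(out)
}

#' @rdname read_seg
#' @param segments Segment tibble (0-based half-open).
#' @export
write_seg <- function(segments, path) {
  out <- arrange(segments, .data$sample_id, .data$chromosome, .data$start)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read pre-called gene-level CNV statuses
#'
#' @param path Tab-delimited file with columns `sample_id`, `gene`, `status`
#'   (`gain`/`loss`/`neutral`).
#' @return Tibble `sample_id`, `gene`, `status`.
#' @export
read_gene_cnv <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("sample_id", "gene", "status"), "gene-level CNV file")
  bad <- !df$status %in% cnv_states
  if (any(bad)) {
    abort(sprintf("invalid CNV status '%s' at row %d; permitted: %s",
                  df$status[which(bad)[1]], which(bad)[1],
                  paste(cnv_states, collapse = ", ")))
  }
  tibble(sample_id = df$sample_id, gene = df$gene, status = df$status)
}

#' Read chromosome-arm intervals from a cytoBand-style file
#'
#' Bands are merged per chromosome into one `p` and one `q` interval (the
#' hull of the bands whose name starts with that letter; acen/gvar bands
#' count toward their named arm). Chromosomes lacking a `p` or `q` band emit
#' a warning and only the present arm.
#'
#' @param path cytoBand file: tab-delimited `chrom`, `start`, `end`, `band`,
#'   `stain`, no header.
#' @return Tibble `chromosome`, `arm` (`"p"`/`"q"`), `start`, `end`
#'   (0-based half-open), plus `arm_label` like `"8q"`.
#' @export
read_cytoband_arms <- function(path) {
  df <- read_tsv_quiet(path, col_names = c("chrom", "start", "end", "band", "stain"),
                       col_types = "ciicc")
  df$chromosome <- normalize_chromosome(df$chrom)
  df$arm <- substr(df$band, 1, 1)
  df <- df[df$arm %in% c("p", "q"), , drop = FALSE]
  arms <- df |>
    group_by(.data$chromosome, .data$arm) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$chromosome, .data$arm)
  one_armed <- arms |>
    count(.data$chromosome) |>
    filter(.data$n < 2)
  if (nrow(one_armed) > 0) {
    warn(sprintf("chromosome(s) missing a p or q band: %s (arm omitted)",
                 paste(one_armed$chromosome, collapse = ", ")))
  }
  arms |> mutate(arm_label = paste0(.data$chromosome, .data$arm))
}

#' Read a panel gene list with coordinates from a BED file
#'
#' @param path BED file (`chrom`, `start`, `end`, `name`), 0-based half-open.
#' @return Tibble `gene`, `chromosome`, `start`, `end`. Gene symbols must be
#'   unique.
#' @export
read_bed_panel <- function(path) {
  df <- read_tsv_quiet(path, col_names = c("chrom", "start", "end", "name"),
                       col_types = "ciic")
  dup <- df$name[duplicated(df$name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated panel gene symbol(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  tibble(gene = df$name, chromosome = normalize_chromosome(df$chrom),
         start = df$start, end = df$end)
}

#' @rdname read_bed_panel
#' @param genes Gene coordinate tibble.
#' @export
write_bed_panel <- function(genes, path) {
  out <- genes |>
    arrange(.data$chromosome, .data$start) |>
    select("chromosome", "start", "end", "gene")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>gene...`.
#' @return Named list of character vectors; descriptions kept as an
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) abort("GMT line with fewer than 3 fields (empty gene set)")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read reference signature spectra (SBS96 TSV)
#'
#' @param path TSV with a `Type` column holding the 96 SBS class labels and
#'   one column per reference signature. Columns are renormalized to sum
#'   to 1.
#' @return 96 x S numeric matrix, rownames in canonical SBS96 order.
#' @export
read_signature_reference <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, "Type", "signature reference file")
  types <- sbs96_types()
  if (nrow(df) != 96 || !setequal(df$Type, types)) {
    abort("signature reference must have exactly the 96 SBS96 types")
  }
  m <- as.matrix(df[, setdiff(names(df), "Type"), drop = FALSE])
  rownames(m) <- df$Type
  m <- m[types, , drop = FALSE]
  cs <- colSums(m)
  if (any(cs <= 0)) abort("signature reference column sums to zero")
  sweep(m, 2, cs, "/")
}

#' @rdname read_signature_reference
#' @param spectra 96 x S matrix with SBS96 rownames.
#' @export
write_signature_reference <- function(spectra, path) {
  df <- bind_cols(tibble(Type = rownames(spectra)),
                  as_tibble(as.data.frame(spectra)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' @param path TSV with a `gene` column followed by one column per sample;
#'   values are non-negative normalized expression.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, "gene", "expression file")
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated gene symbol(s) in expression file: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) abort("expression values must be non-negative")
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression
#' @param expr Gene-by-sample matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  df <- bind_cols(tibble(gene = rownames(expr)),
                  as_tibble(as.data.frame(expr)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a sample-to-cohort label table
#'
#' @param path TSV with columns `sample_id`, `cohort`.
#' @return Tibble `sample_id`, `cohort`.
#' @export
read_samples <- function(path) {
  df <- read_tsv_quiet(path, col_types = "cc")
  require_columns(df, c("sample_id", "cohort"), "sample table")
  as_tibble(df[, c("sample_id", "cohort")])
}

#' @rdname read_samples
#' @param samples Sample tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(arrange(samples, .data$sample_id), path, progress = FALSE)
  invisible(path)
}

# resolve and validate the two cohort labels of a sample table; the first
# label is "cohort 1" (numerator of odds ratios / fold changes)
cohort_pair <- function(samples, cohort_order = NULL) {
  labs <- unique(samples$cohort)
  if (length(labs) != 2) {
    abort(sprintf("expected exactly 2 cohorts, found %d", length(labs)))
  }
  if (is.null(cohort_order)) sort(labs)
  else {
    if (!setequal(cohort_order, labs)) abort("cohort_order must name both cohorts")
    cohort_order
  }
}
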