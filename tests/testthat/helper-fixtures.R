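# Shared fixture builders: everything is generated in code at test time.

# variant tibble with sensible defaults, overridable per-column
make_variants <- function(n = 1, ...) {
  base <- tibble::tibble(
    sample_id = rep("S1", n), gene = rep("G001", n),
    classification = rep("missense", n), chromosome = rep("1", n),
    position = seq_len(n) * 10, ref = rep("C", n), alt = rep("T", n),
    popmax_af = rep(NA_real_, n), context = rep("ACA", n)
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# write a minimal MAF file; returns the path
write_maf_text <- function(rows, path = tempfile(fileext = ".maf"),
                           extra_cols = NULL) {
  header <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
              "Chromosome", "Start_Position", "Reference_Allele",
              "Tumor_Seq_Allele2", names(extra_cols))
  lines <- c("# fixture", paste(header, collapse = "\t"), rows)
  writeLines(lines, path)
  path
}

make_samples <- function(n1 = 3, n2 = 3, cohorts = c("A", "B")) {
  tibble::tibble(
    sample_id = c(sprintf("%s%02d", cohorts[1], seq_len(n1)),
                  sprintf("%s%02d", cohorts[2], seq_len(n2))),
    cohort = rep(cohorts, c(n1, n2))
  )
}

# mutation_matrix with given per-gene mutated counts in each cohort
make_mm <- function(counts1, counts2, n1, n2, genes = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_along(counts1))
  samples <- make_samples(n1, n2)
  m <- matrix(0L, length(genes), n1 + n2,
              dimnames = list(genes, samples$sample_id))
  for (i in seq_along(genes)) {
    if (counts1[i] > 0) m[i, seq_len(counts1[i])] <- 1L
    if (counts2[i] > 0) m[i, n1 + seq_len(counts2[i])] <- 1L
  }
  structure(list(indicator = m, samples = samples), class = "mutation_matrix")
}

# small gene/arm annotation: n genes on 2 chromosomes with p/q arms
make_annotation <- function(n_genes = 8) {
  genes <- tibble::tibble(
    gene = sprintf("G%03d", seq_len(n_genes)),
    chromosome = rep(c("1", "2"), length.out = n_genes),
    start = 1000 + 2000 * (seq_len(n_genes) - 1),
    end = 2000 + 2000 * (seq_len(n_genes) - 1)
  )
  arms <- tibble::tibble(
    chromosome = rep(c("1", "2"), each = 2), arm = rep(c("p", "q"), 2),
    start = rep(c(0, 10000), 2), end = rep(c(10000, 40000), 2)
  ) |> dplyr::mutate(arm_label = paste0(chromosome, arm))
  list(genes = genes, arms = arms)
}

# random 3-spectrum SBS96 catalog with mixture weights; used by signature tests
make_signature_study <- function(seed, n_samples = 120, n_mut = 150,
                                 cosine_cap = 0.6, weight_means = c(1, 1, 1)) {
  set.seed(seed)
  repeat {
    S <- matrix(rgamma(96 * 3, 0.15), 96)
    S <- sweep(S, 2, colSums(S), "/")
    pairs <- utils::combn(3, 2)
    ok <- all(apply(pairs, 2, function(ij) {
      cosine_similarity(S[, ij[1]], S[, ij[2]])
    }) <= cosine_cap)
    if (ok) break
  }
  rownames(S) <- sbs96_types()
  colnames(S) <- paste0("TrueSig", 1:3)
  W <- vapply(seq_len(n_samples), function(i) {
    w <- rgamma(3, shape = 2, scale = weight_means / 2)
    w / sum(w)
  }, numeric(3))
  catalog <- t(vapply(seq_len(n_samples), function(i) {
    as.integer(rmultinom(1, n_mut, S %*% W[, i, drop = FALSE]))
  }, integer(96)))
  colnames(catalog) <- sbs96_types()
  rownames(catalog) <- sprintf("s%03d", seq_len(n_samples))
  list(spectra = S, weights = W, catalog = catalog)
}
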