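# Synthetic two-cohort multi-omics study generator with a ground-truth
# ledger. Emulates the study design: a small cohort (A) profiled at segment
# level against a large comparator (B) observed at gene level, with planted
# differential mutation genes, broad arm gains concentrated in cohort B,
# focal losses concentrated in cohort A, platform-distorted expression with
# planted DEGs, and mutation catalogs drawn from mixtures of known spectra
# with group-shifted exposures.

#' Default configuration for the synthetic study
#'
#' Returns the full parameter list of the generator. Defaults follow the
#' emulated study design: cohorts of 17 vs 689 samples, a 648-gene panel on
#' 22 autosomes with p/q arms, 11 planted differentially mutated genes at
#' per-sample rates 0.24 vs 0.02 over a 0.02 background, broad arm gains
#' dominant in cohort B (per-arm probabilities 6.24/44 vs 20.73/44), focal
#' losses dominant in cohort A (12 planted genes at 0.35 vs 0.05, on top of
#' a shared diffuse per-gene loss background of 0.008 that keeps the
#' arm-loss burden of cohort B near 5 arms per sample), asymmetric
#' planted DEGs (40 up in A, 12 up in B, fold 8) under cohort-specific
#' monotone platform distortion, and three signature spectra of which two
#' have exposures shifted toward cohort B.
#'
#' @param n_A,n_B Cohort sizes.
#' @param seed Integer seed driving every random draw.
#' @param ... Named overrides of any default listed above (see the returned
#'   list for the full set).
#' @return Named list of generator parameters.
#' @export
simulation_config <- function(n_A = 17, n_B = 689, seed = 1L, ...) {
  cfg <- list(
    n_A = n_A, n_B = n_B, seed = seed,
    cohort_names = c("A", "B"),
    panel_size = 648, n_chromosomes = 22,
    # mutation layer
    baseline_mutation_rate = 0.02,
    n_planted_mutation_genes = 11,
    planted_rate_A = 0.24, planted_rate_B = 0.02,
    snv_fraction = 0.9, decoy_fraction = 0.05,
    # SNVs per mutated gene: cohort B carries the higher mutational burden
    # (its shifted signature exposures add mutations; see exposure means)
    snv_per_gene_A = 1:3, snv_per_gene_B = 3:7,
    # CNV layer: broad gains dominate cohort B; focal losses dominate A on
    # top of a shared diffuse loss background
    arm_gain_prob_A = 6.24 / 44, arm_gain_prob_B = 20.73 / 44,
    n_focal_loss_genes = 12,
    focal_loss_rate_A = 0.35, focal_loss_rate_B = 0.05,
    diffuse_loss_rate = 0.008,
    # expression layer
    expr_meanlog = log(100), expr_sdlog = 1,
    n_deg_up_A = 40, n_deg_up_B = 12, deg_fold = 8,
    expr_noise_sdlog = 0.5,
    platform_power = c(A = 1.0, B = 0.92),
    platform_scale = c(A = 1.0, B = 1.2),
    # signature layer
    n_signatures = 3, spectra_cosine_cap = 0.6,
    exposure_mean_A = c(5, 5, 20), exposure_mean_B = c(20, 20, 20),
    exposure_shape = 2,
    # pathway layer
    n_pathways = 15, pathway_size = 25
  )
  modifyList(cfg, list(...))
}

# deterministic synthetic genome annotation: 22 small chromosomes with p/q
# arms separated by an acen band pair, panel genes spaced inside the arms
make_genome_annotation <- function(panel_size, n_chromosomes = 22) {
  chrom_len <- 200000
  cyto <- purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
    tibble(chrom = as.character(ch),
           start = c(0, 30000, 60000, 95000, 130000, 165000),
           end = c(30000, 60000, 95000, 130000, 165000, chrom_len),
           band = c("p13", "p12", "p11", "q11", "q12", "q13"),
           stain = c("gneg", "gpos50", "acen", "acen", "gneg", "gpos50"))
  })
  arm_bounds <- list(p = c(0, 95000), q = c(95000, chrom_len))
  chrom_of <- rep(seq_len(n_chromosomes), length.out = panel_size)
  genes <- purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
    idx <- which(chrom_of == ch)
    n <- length(idx)
    n_p <- ceiling(n / 2)
    arm <- c(rep("p", n_p), rep("q", n - n_p))
    within <- c(seq_len(n_p), seq_len(n - n_p))
    start <- ifelse(arm == "p", 2000, 102000) + (within - 1) * 5500
    tibble(gene = sprintf("G%03d", idx), chromosome = as.character(ch),
           start = start, end = start + 2000, arm = arm)
  }) |> arrange(.data$gene)
  list(cytoband = cyto, genes = genes, chrom_len = chrom_len,
       arm_bounds = arm_bounds)
}

# three (or n) sparse SBS96 spectra with pairwise cosine below a cap
generate_spectra <- function(n, cosine_cap, concentration = 0.15) {
  for (try in 1:200) {
    S <- matrix(rgamma(96 * n, shape = concentration), nrow = 96)
    S <- sweep(S, 2, colSums(S), "/")
    cos_ok <- TRUE
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (cosine_similarity(S[, i], S[, j]) > cosine_cap) cos_ok <- FALSE
      }
    }
    if (cos_ok) {
      rownames(S) <- sbs96_types()
      colnames(S) <- paste0("RefSig", seq_len(n))
      return(S)
    }
  }
  abort("could not generate spectra under the cosine cap")
}

parse_sbs96 <- function(cls) {
  tibble(five = substr(cls, 1, 1), ref = substr(cls, 3, 3),
         alt = substr(cls, 5, 5), three = substr(cls, 7, 7),
         context = paste0(substr(cls, 1, 1), substr(cls, 3, 3),
                          substr(cls, 7, 7)))
}

#' Simulate a complete two-cohort multi-omics study on disk
#'
#' Writes every input file the pipeline consumes — MAF per cohort (with a
#' trinucleotide-context column), segment-level CNV for cohort A and
#' pre-called gene-level CNV for cohort B (exercising both ingestion
#' paths), a gene-by-sample expression matrix with cohort labels, the panel
#' BED, a cytoBand-style arm file, a gene-set GMT with planted pathways, the
#' true signature spectra as a reference TSV, a small synthetic FASTA
#' consistent with the chromosome-1 variant contexts — plus a machine-
#' readable truth ledger (JSON) recording every planted effect. All output
#' is reproducible from the config seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()] list.
#' @return Invisibly, a list with `paths` (named file paths) and `ledger`
#'   (the truth ledger, also written as JSON).
#' @export
simulate_study <- function(out_dir, config = simulation_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  set.seed(cfg$seed)
  ann <- make_genome_annotation(cfg$panel_size, cfg$n_chromosomes)
  genes <- ann$genes
  panel <- genes$gene
  cohorts <- cfg$cohort_names
  ids_A <- sprintf("%s%03d", cohorts[1], seq_len(cfg$n_A))
  ids_B <- sprintf("%s%03d", cohorts[2], seq_len(cfg$n_B))
  samples <- tibble(sample_id = c(ids_A, ids_B),
                    cohort = rep(cohorts, c(cfg$n_A, cfg$n_B)))

  # ---- planted entities -------------------------------------------------
  planted_mut <- sort(sample(panel, cfg$n_planted_mutation_genes))
  # focal-loss genes on distinct arms, disjoint from the mutation genes
  arms_all <- genes |>
    mutate(arm_label = paste0(.data$chromosome, .data$arm)) |>
    filter(!.data$gene %in% planted_mut)
  focal_pool <- arms_all |>
    group_by(.data$arm_label) |>
    dplyr::slice_sample(n = 1) |>
    ungroup()
  planted_loss <- sort(sample(focal_pool$gene,
                              min(cfg$n_focal_loss_genes, nrow(focal_pool))))
  deg_pool <- setdiff(panel, c(planted_mut, planted_loss))
  deg_up_A <- sort(sample(deg_pool, cfg$n_deg_up_A))
  deg_up_B <- sort(sample(setdiff(deg_pool, deg_up_A), cfg$n_deg_up_B))
  spectra <- generate_spectra(cfg$n_signatures, cfg$spectra_cosine_cap)

  # per-sample exposure weights (gamma with cohort means, fixed shape)
  draw_weights <- function(n, means) {
    t(vapply(seq_len(n), function(i) {
      w <- rgamma(length(means), shape = cfg$exposure_shape,
                  scale = means / cfg$exposure_shape)
      w / sum(w)
    }, numeric(length(means))))
  }
  w_A <- draw_weights(cfg$n_A, cfg$exposure_mean_A)
  w_B <- draw_weights(cfg$n_B, cfg$exposure_mean_B)
  weights <- rbind(w_A, w_B)
  rownames(weights) <- samples$sample_id
  colnames(weights) <- colnames(spectra)

  # ---- mutation layer ---------------------------------------------------
  slot_counter <- new.env(parent = emptyenv())
  chr1_contexts <- list()
  next_position <- function(gene_row, context) {
    key <- gene_row$gene
    idx <- get0(key, slot_counter, ifnotfound = 0L)
    assign(key, idx + 1L, slot_counter)
    pos <- gene_row$start + 3L * idx + 2L     # 1-based, 3-mer stays in-gene
    if (gene_row$chromosome == "1") {
      chr1_contexts[[length(chr1_contexts) + 1]] <<- list(pos = pos,
                                                          context = context)
    }
    pos
  }
  gene_idx <- setNames(seq_len(nrow(genes)), genes$gene)
  snv_classes <- c("missense", "nonsense", "splice_site")
  indel_classes <- c("frameshift_del", "frameshift_ins", "inframe_del",
                     "inframe_ins")

  make_variants <- function(ids, rate_planted, weights_m, snv_range) {
    rows <- list()
    for (s in seq_along(ids)) {
      sid <- ids[s]
      rate <- ifelse(panel %in% planted_mut, rate_planted,
                     cfg$baseline_mutation_rate)
      hit <- which(runif(length(panel)) < rate)
      for (g in hit) {
        grow <- genes[gene_idx[[panel[g]]], ]
        n_mut <- if (length(snv_range) == 1) snv_range else sample(snv_range, 1)
        for (m in seq_len(n_mut)) {
          if (runif(1) < cfg$snv_fraction) {
            sig <- sample(ncol(spectra), 1, prob = weights_m[sid, ])
            cls96 <- sample(rownames(spectra), 1, prob = spectra[, sig])
            pc <- parse_sbs96(cls96)
            ref <- pc$ref; alt <- pc$alt; ctx <- pc$context
            if (runif(1) < 0.5) {   # purine-strand representation
              ref <- chartr("ACGT", "TGCA", ref)
              alt <- chartr("ACGT", "TGCA", alt)
              ctx <- revcomp(ctx)
            }
            pos <- next_position(grow, ctx)
            rows[[length(rows) + 1]] <- tibble(
              sample_id = sid, gene = grow$gene,
              classification = sample(snv_classes, 1,
                                      prob = c(0.8, 0.12, 0.08)),
              chromosome = grow$chromosome, position = pos,
              ref = ref, alt = alt,
              popmax_af = if (runif(1) < 0.5) NA_real_ else runif(1, 0, 4e-4),
              context = ctx
            )
          } else {                  # indel: no SBS class, skipped by catalog
            pos <- next_position(grow, "NNN")
            rows[[length(rows) + 1]] <- tibble(
              sample_id = sid, gene = grow$gene,
              classification = sample(indel_classes, 1),
              chromosome = grow$chromosome, position = pos,
              ref = "AC", alt = "A", popmax_af = NA_real_,
              context = NA_character_
            )
          }
        }
      }
    }
    bind_rows(rows)
  }

  make_decoys <- function(ids, n_real) {
    n_each <- max(1L, round(cfg$decoy_fraction * n_real / 3))
    if (cfg$decoy_fraction == 0) return(empty_variants())
    one <- function(kind) {
      purrr::map_dfr(seq_len(n_each), function(i) {
        grow <- genes[sample(nrow(genes), 1), ]
        pos <- next_position(grow, "ACA")
        tibble(
          sample_id = sample(ids, 1),
          gene = if (kind == "off_panel") sprintf("OFFP%02d", i) else grow$gene,
          classification = if (kind == "silent") "silent" else "missense",
          chromosome = grow$chromosome, position = pos,
          ref = "C", alt = "T",
          popmax_af = if (kind == "high_af") runif(1, 0.001, 0.05) else NA_real_,
          context = "ACA"
        )
      })
    }
    bind_rows(one("high_af"), one("silent"), one("off_panel"))
  }

  var_A <- make_variants(ids_A, cfg$planted_rate_A, weights, cfg$snv_per_gene_A)
  var_B <- make_variants(ids_B, cfg$planted_rate_B, weights, cfg$snv_per_gene_B)
  var_A <- bind_rows(var_A, make_decoys(ids_A, nrow(var_A)))
  var_B <- bind_rows(var_B, make_decoys(ids_B, nrow(var_B)))

  # ---- CNV layer --------------------------------------------------------
  arms_tbl <- read_arms_from_cyto(ann$cytoband)
  gene_arm <- genes |> mutate(arm_label = paste0(.data$chromosome, .data$arm))
  # cohort A: segment-level; whole-arm gain or neutral segments plus short
  # focal loss segments over planted genes
  seg_rows <- purrr::map_dfr(ids_A, function(sid) {
    arm_events <- arms_tbl |>
      mutate(state = ifelse(runif(dplyr::n()) < cfg$arm_gain_prob_A,
                            "gain", "neutral"))
    segs <- tibble(sample_id = sid, chromosome = arm_events$chromosome,
                   start = arm_events$start, end = arm_events$end,
                   state = arm_events$state)
    loss_p <- ifelse(genes$gene %in% planted_loss,
                     cfg$focal_loss_rate_A + cfg$diffuse_loss_rate,
                     cfg$diffuse_loss_rate)
    focal <- genes[runif(nrow(genes)) < loss_p, , drop = FALSE]
    if (nrow(focal) > 0) {
      segs <- bind_rows(segs, tibble(
        sample_id = sid, chromosome = focal$chromosome,
        start = pmax(0, focal$start - 100), end = focal$end + 100,
        state = "loss"
      ))
    }
    segs
  })
  # cohort B: pre-called gene-level statuses
  gene_cnv_B <- purrr::map_dfr(ids_B, function(sid) {
    gained_arms <- arms_tbl$arm_label[runif(nrow(arms_tbl)) < cfg$arm_gain_prob_B]
    st <- ifelse(gene_arm$arm_label %in% gained_arms, "gain", "neutral")
    loss_p <- ifelse(gene_arm$gene %in% planted_loss,
                     cfg$focal_loss_rate_B + cfg$diffuse_loss_rate,
                     cfg$diffuse_loss_rate)
    st[runif(nrow(gene_arm)) < loss_p] <- "loss"
    tibble(sample_id = sid, gene = gene_arm$gene, status = st)
  })

  # ---- expression layer -------------------------------------------------
  mu <- rlnorm(length(panel), cfg$expr_meanlog, cfg$expr_sdlog)
  names(mu) <- panel
  fold_mat <- matrix(1, nrow = length(panel), ncol = nrow(samples),
                     dimnames = list(panel, samples$sample_id))
  fold_mat[deg_up_A, ids_A] <- cfg$deg_fold
  fold_mat[deg_up_B, ids_B] <- cfg$deg_fold
  noise <- matrix(rlnorm(length(fold_mat), 0, cfg$expr_noise_sdlog),
                  nrow = nrow(fold_mat))
  expr <- mu * fold_mat * noise
  for (co in cohorts) {
    cols <- samples$sample_id[samples$cohort == co]
    expr[, cols] <- cfg$platform_scale[[co]] * expr[, cols]^cfg$platform_power[[co]]
  }

  # ---- pathway layer ----------------------------------------------------
  n_random <- cfg$n_pathways - 3
  half <- ceiling(length(deg_up_A) / 2)
  sets <- list(
    PW_PLANTED_DEG1 = sort(c(deg_up_A[seq_len(half)],
                             sample(setdiff(panel, deg_up_A), 5))),
    PW_PLANTED_DEG2 = sort(c(deg_up_A[seq(half + 1, length(deg_up_A))],
                             sample(setdiff(panel, deg_up_A), 5))),
    PW_PLANTED_MUT = sort(c(planted_mut,
                            sample(setdiff(panel, planted_mut), 10)))
  )
  for (i in seq_len(n_random)) {
    sets[[sprintf("PW_RANDOM%02d", i)]] <- sort(sample(panel, cfg$pathway_size))
  }
  attr(sets, "description") <- setNames(rep("synthetic pathway", length(sets)),
                                        names(sets))

  # ---- chromosome-1 FASTA consistent with the emitted contexts ----------
  seq1 <- sample(dna_bases, ann$chrom_len, replace = TRUE)
  for (cc in chr1_contexts) {
    if (cc$context == "NNN") next
    seq1[(cc$pos - 1):(cc$pos + 1)] <- strsplit(cc$context, "")[[1]]
  }

  # ---- write everything -------------------------------------------------
  paths <- list(
    maf_a = file.path(out_dir, "cohortA.maf"),
    maf_b = file.path(out_dir, "cohortB.maf"),
    seg_a = file.path(out_dir, "cohortA.seg"),
    gene_cnv_b = file.path(out_dir, "cohortB_gene_cnv.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    panel_bed = file.path(out_dir, "panel.bed"),
    cytoband = file.path(out_dir, "cytoband.tsv"),
    gmt = file.path(out_dir, "genesets.gmt"),
    reference_spectra = file.path(out_dir, "reference_spectra.tsv"),
    fasta = file.path(out_dir, "chr1_synthetic.fa"),
    truth = file.path(out_dir, "truth_ledger.json")
  )
  write_maf(var_A, paths$maf_a)
  write_maf(var_B, paths$maf_b)
  write_seg(seg_rows, paths$seg_a)
  readr::write_tsv(arrange(gene_cnv_B, .data$sample_id, .data$gene),
                   paths$gene_cnv_b, progress = FALSE)
  write_expression(round(expr, 6), paths$expression)
  write_samples(samples, paths$samples)
  write_bed_panel(genes, paths$panel_bed)
  readr::write_tsv(ann$cytoband, paths$cytoband, col_names = FALSE,
                   progress = FALSE)
  write_gmt(sets, paths$gmt)
  write_signature_reference(spectra, paths$reference_spectra)
  writeLines(c(">1 synthetic", vapply(seq(1, ann$chrom_len, 80), function(i) {
    paste(seq1[i:min(i + 79, ann$chrom_len)], collapse = "")
  }, "")), paths$fasta)

  ledger <- list(
    seed = cfg$seed, cohorts = cohorts,
    n_A = cfg$n_A, n_B = cfg$n_B,
    planted_mutation_genes = planted_mut,
    planted_mutation_rates = list(A = cfg$planted_rate_A,
                                  B = cfg$planted_rate_B),
    baseline_mutation_rate = cfg$baseline_mutation_rate,
    arm_gain_prob = list(A = cfg$arm_gain_prob_A, B = cfg$arm_gain_prob_B),
    planted_focal_loss_genes = planted_loss,
    focal_loss_rate = list(A = cfg$focal_loss_rate_A,
                           B = cfg$focal_loss_rate_B),
    planted_deg_up_A = deg_up_A, planted_deg_up_B = deg_up_B,
    deg_fold = cfg$deg_fold,
    signature_spectra = as.data.frame(spectra),
    exposure_weights = as.data.frame(weights),
    exposure_mean = list(A = cfg$exposure_mean_A, B = cfg$exposure_mean_B),
    shifted_signatures = colnames(spectra)[cfg$exposure_mean_B >
                                             cfg$exposure_mean_A],
    planted_pathways = list(deg = c("PW_PLANTED_DEG1", "PW_PLANTED_DEG2"),
                            mutation = "PW_PLANTED_MUT")
  )
  jsonlite::write_json(ledger, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, ledger = ledger))
}

# arms tibble from an in-memory cytoband table (same logic as the reader)
read_arms_from_cyto <- function(cyto) {
  cyto |>
    mutate(chromosome = normalize_chromosome(.data$chrom),
           arm = substr(.data$band, 1, 1)) |>
    filter(.data$arm %in% c("p", "q")) |>
    group_by(.data$chromosome, .data$arm) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(arm_label = paste0(.data$chromosome, .data$arm)) |>
    arrange(.data$chromosome, .data$arm)
}
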