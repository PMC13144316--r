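# End-to-end orchestration: filter -> mutation -> CNV -> expression ->
# signatures -> enrichment, from a single config, with a deterministic
# manifest.

#' Default pipeline configuration
#'
#' @param inputs Named list of input file paths (`maf_a`, `maf_b`, `seg_a`,
#'   `gene_cnv_b`, `expression`, `samples`, `panel_bed`, `cytoband`, `gmt`,
#'   `reference_spectra`), e.g. the `paths` element returned by
#'   [simulate_study()].
#' @param ... Overrides of the analysis defaults: `af_threshold` (5e-4),
#'   `mutation_fdr` (0.1), `cnv_fdr` (0.05), `arm_fdr` (0.05), `deg_p`
#'   (0.01), `lfc_threshold` (2), `expr_threshold` (10), `pseudocount` (1),
#'   `k_min` (1), `k_max` (10), `n_replicates` (20), `bootstrap_n` (5000),
#'   `seed` (1), `stages` (all five), `out_dir` (NULL = no files written).
#' @return Config list accepted by [run_all()].
#' @export
pipeline_config <- function(inputs, ...) {
  cfg <- list(
    inputs = inputs,
    af_threshold = 0.0005, mutation_fdr = 0.1,
    cnv_fdr = 0.05, arm_fdr = 0.05,
    deg_p = 0.01, lfc_threshold = 2, expr_threshold = 10, pseudocount = 1,
    k_min = 1, k_max = 10, n_replicates = 20, stability_floor = 0.8,
    bootstrap_n = 5000, seed = 1L,
    stages = c("mutation", "cnv", "expression", "mutsig", "enrichment"),
    out_dir = NULL
  )
  modifyList(cfg, list(...))
}

#' Run the whole race-stratified comparison pipeline
#'
#' Executes the requested stages in order (variant filtering and mutation
#' tests, CNV gene/arm/burden tests, rank-based differential expression,
#' signature extraction and exposure comparison, per-layer enrichment and
#' the integrative matrix). Any stage can be skipped via `config$stages`;
#' the enrichment stage consumes whichever upstream layers ran. If
#' `config$out_dir` is set, every result table is written as TSV/JSON along
#' with a deterministic run manifest (config hash, seed, thresholds, input
#' and output digests); wall-clock timings go to a separate log file so the
#' manifest hash is reproducible across reruns.
#'
#' @param config A [pipeline_config()] list, or the path to a YAML file with
#'   the same structure.
#' @return List of stage results (invisibly returns the same list when
#'   writing to disk): `filter`, `mutation`, `cnv`, `expression`, `mutsig`,
#'   `enrichment`, `manifest`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_config(config$inputs), config)
  inp <- cfg$inputs
  need <- c("samples", "panel_bed")
  if ("mutation" %in% cfg$stages || "mutsig" %in% cfg$stages) {
    need <- c(need, "maf_a", "maf_b")
  }
  if ("cnv" %in% cfg$stages) need <- c(need, "seg_a", "gene_cnv_b", "cytoband")
  if ("expression" %in% cfg$stages) need <- c(need, "expression")
  if ("mutsig" %in% cfg$stages) need <- c(need, "reference_spectra")
  if ("enrichment" %in% cfg$stages) need <- c(need, "gmt")
  missing_in <- need[!vapply(need, function(nm) {
    !is.null(inp[[nm]]) && file.exists(inp[[nm]])
  }, TRUE)]
  if (length(missing_in) > 0) {
    abort(sprintf("missing input(s) for requested stages: %s",
                  paste(unique(missing_in), collapse = ", ")))
  }

  samples <- read_samples(inp$samples)
  genes <- read_bed_panel(inp$panel_bed)
  panel <- genes$gene
  cohorts <- cohort_pair(samples)
  results <- list()
  timings <- list()
  stamp <- function(stage, t0) {
    timings[[stage]] <<- round(as.numeric(Sys.time()) - t0, 3)
  }

  # --- variant filtering (shared by mutation and mutsig stages) ----------
  filtered <- NULL
  if (any(c("mutation", "mutsig") %in% cfg$stages)) {
    t0 <- as.numeric(Sys.time())
    raw_a <- read_maf(inp$maf_a)
    raw_b <- read_maf(inp$maf_b)
    fa <- run_filter_cascade(raw_a, panel, cfg$af_threshold)
    fb <- run_filter_cascade(raw_b, panel, cfg$af_threshold)
    filtered <- bind_rows(fa$variants, fb$variants)
    results$filter <- list(report_a = fa$report, report_b = fb$report)
    stamp("filter", t0)
  }

  if ("mutation" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    mm <- build_mutation_matrix(filtered, samples, panel)
    tests <- test_gene_frequencies(mm, fdr_threshold = cfg$mutation_fdr)
    sig_genes <- tests$gene[tests$significant]
    boots <- purrr::map_dfr(sig_genes, function(g) {
      bootstrap_log_or(mm, g, n_resamples = cfg$bootstrap_n, seed = cfg$seed)
    })
    results$mutation <- list(matrix = mm, tests = tests, bootstrap = boots,
                             oncotable = oncotable(filtered, samples, panel))
    stamp("mutation", t0)
  }

  if ("cnv" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    arms <- read_cytoband_arms(inp$cytoband)
    samples_a <- filter(samples, .data$cohort == cohorts[1])
    samples_b <- filter(samples, .data$cohort == cohorts[2])
    gc_a <- assign_gene_status(read_seg(inp$seg_a), genes, samples_a)
    gc_b <- as_gene_cnv(read_gene_cnv(inp$gene_cnv_b), genes, samples_b)
    gene_cnv <- bind_rows(gc_a, gc_b)
    gene_tests <- lapply(
      setNames(c("gain", "loss", "change"), c("gain", "loss", "change")),
      function(ev) test_cnv_frequencies(gene_cnv, samples, ev, cfg$cnv_fdr)
    )
    arm_table <- collapse_to_arms(gene_cnv, genes, arms)
    arm_tests <- test_arm_frequencies(arm_table, samples, cfg$arm_fdr)
    burden <- compare_burden(arm_table, samples)
    results$cnv <- list(gene_cnv = gene_cnv, gene_tests = gene_tests,
                        arm_table = arm_table, arm_tests = arm_tests,
                        burden = burden)
    stamp("cnv", t0)
  }

  if ("expression" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    expr <- read_expression(inp$expression)
    expr_samples <- filter(samples, .data$sample_id %in% colnames(expr))
    deg <- run_expression_diff(expr, expr_samples,
                               threshold = cfg$expr_threshold,
                               p_threshold = cfg$deg_p,
                               lfc_threshold = cfg$lfc_threshold,
                               pseudocount = cfg$pseudocount)
    results$expression <- list(deg = deg,
                               universe = deg$gene)
    stamp("expression", t0)
  }

  if ("mutsig" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    catalog <- build_catalog(filtered, samples, context_source = "column")
    model <- extract_signatures(catalog, k_min = cfg$k_min, k_max = cfg$k_max,
                                n_replicates = cfg$n_replicates,
                                seed = cfg$seed,
                                stability_floor = cfg$stability_floor)
    reference <- read_signature_reference(inp$reference_spectra)
    decomposition <- decompose_to_reference(model, reference)
    exposure_tests <- compare_exposures(model, samples)
    results$mutsig <- list(catalog = catalog, model = model,
                           decomposition = decomposition,
                           exposure_tests = exposure_tests)
    stamp("mutsig", t0)
  }

  if ("enrichment" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    collection <- read_gmt(inp$gmt)
    layers <- list()
    if (!is.null(results$mutation)) {
      mt <- results$mutation$tests
      q1 <- mt$gene[mt$significant & mt$enriched_cohort %in% cohorts[1]]
      if (length(q1) > 0) {
        layers[[paste0("Mutation_", cohorts[1])]] <-
          run_ora(q1, collection, panel)
      }
    }
    if (!is.null(results$expression)) {
      deg <- results$expression$deg
      uni <- results$expression$universe
      for (i in 1:2) {
        qq <- deg$gene[deg$deg & deg$direction == paste0("up_", i)]
        if (length(qq) > 0) {
          layers[[paste0("DEG_Up_", cohorts[i])]] <-
            run_ora(qq, collection, uni)
        }
      }
    }
    if (!is.null(results$cnv)) {
      for (ev in c("gain", "loss")) {
        tt <- results$cnv$gene_tests[[ev]]
        for (i in 1:2) {
          qq <- tt$gene[tt$significant & tt$enriched_cohort %in% cohorts[i]]
          if (length(qq) > 0) {
            layers[[sprintf("CNV_%s_%s", tools::toTitleCase(ev), cohorts[i])]] <-
              run_ora(qq, collection, panel)
          }
        }
      }
    }
    results$enrichment <- list(
      layers = layers,
      integrative = if (length(layers) > 0) build_integrative_matrix(layers)
                    else NULL
    )
    stamp("enrichment", t0)
  }

  results$manifest <- build_manifest(cfg, results)
  if (!is.null(cfg$out_dir)) {
    write_bundle(results, cfg, timings)
  }
  invisible(results)
}

# the config hash covers the analysis parameters; input *content* is
# captured separately by the per-file digests, so file locations do not
# perturb the hash
strip_inputs_hash <- function(cfg) {
  cfg$out_dir <- NULL
  cfg$inputs <- NULL
  cfg
}

build_manifest <- function(cfg, results) {
  thresholds <- cfg[c("af_threshold", "mutation_fdr", "cnv_fdr", "arm_fdr",
                      "deg_p", "lfc_threshold", "expr_threshold",
                      "k_min", "k_max", "n_replicates", "bootstrap_n")]
  in_files <- unlist(cfg$inputs)
  in_files <- in_files[file.exists(in_files)]
  list(
    package_version = as.character(utils::packageVersion("stratomics")),
    config_hash = rlang::hash(strip_inputs_hash(cfg)),
    seed = cfg$seed,
    stages = cfg$stages,
    thresholds = thresholds,
    input_digests = as.list(tools::md5sum(in_files))
  )
}

write_bundle <- function(results, cfg, timings) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df <- dplyr::select(as_tibble(df), -dplyr::any_of("overlap_genes"))
    readr::write_tsv(df, file.path(out, name), progress = FALSE)
  }
  if (!is.null(results$filter)) {
    wr(bind_rows(A = results$filter$report_a, B = results$filter$report_b,
                 .id = "cohort"), "filter_report.tsv")
  }
  if (!is.null(results$mutation)) {
    wr(results$mutation$tests, "mutation_tests.tsv")
    wr(results$mutation$oncotable, "oncotable.tsv")
    if (nrow(results$mutation$bootstrap) > 0) {
      wr(results$mutation$bootstrap, "mutation_bootstrap.tsv")
    }
  }
  if (!is.null(results$cnv)) {
    for (ev in names(results$cnv$gene_tests)) {
      wr(results$cnv$gene_tests[[ev]], sprintf("cnv_gene_%s.tsv", ev))
    }
    wr(results$cnv$arm_tests, "cnv_arm_tests.tsv")
    wr(results$cnv$arm_table$burden, "cnv_burden.tsv")
    wr(results$cnv$burden, "cnv_burden_tests.tsv")
  }
  if (!is.null(results$expression)) wr(results$expression$deg, "deg.tsv")
  if (!is.null(results$mutsig)) {
    readr::write_tsv(as_tibble(as.data.frame(results$mutsig$catalog),
                               rownames = "sample_id"),
                     file.path(out, "catalog.tsv"), progress = FALSE)
    write_signature_reference(results$mutsig$model$W,
                              file.path(out, "signatures_W.tsv"))
    readr::write_tsv(as_tibble(as.data.frame(t(results$mutsig$model$H)),
                               rownames = "sample_id"),
                     file.path(out, "exposures_H.tsv"), progress = FALSE)
    wr(results$mutsig$model$diagnostics, "signature_diagnostics.tsv")
    wr(results$mutsig$decomposition, "signature_decomposition.tsv")
    wr(results$mutsig$exposure_tests, "exposure_tests.tsv")
  }
  if (!is.null(results$enrichment$integrative)) {
    wr(results$enrichment$integrative$matrix, "integrative_matrix.tsv")
    wr(results$enrichment$integrative$long, "integrative_long.tsv")
  }
  jsonlite::write_json(results$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
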