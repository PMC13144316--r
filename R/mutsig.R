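# SBS96 mutational signatures: catalog construction, de novo NMF extraction
# with stability-based model selection, reference decomposition, and cohort
# exposure comparison.

#' Build a sample-by-96 SBS catalog from variants
#'
#' Retains single-base substitutions only (indels and multi-nucleotide
#' variants are skipped with a count), classifies each by its pyrimidine-
#' centered substitution and trinucleotide context (purine-reference calls
#' are reverse-complemented), and accumulates counts per sample. The context
#' comes either from the variant tibble's `context` column or from a
#' reference FASTA.
#'
#' @param variants Variant tibble. With `context_source = "column"` the
#'   `context` column must hold the reference-strand 3-mer centered on the
#'   variant.
#' @param samples Optional sample roster; defaults to the samples present in
#'   `variants`. Roster samples without SBS records get all-zero rows.
#' @param context_source `"column"` or `"fasta"`.
#' @param fasta_path Reference FASTA (required for `"fasta"`); needs the
#'   Biostrings package.
#' @return Integer matrix, samples x 96, columns in [sbs96_types()] order.
#' @export
build_catalog <- function(variants, samples = NULL,
                          context_source = c("column", "fasta"),
                          fasta_path = NULL) {
  context_source <- match.arg(context_source)
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% dna_bases & variants$alt %in% dna_bases &
    variants$ref != variants$alt
  n_skip <- sum(!is_snv)
  if (n_skip > 0) {
    inform(sprintf("skipped %d non-SBS record(s) for the catalog", n_skip))
  }
  v <- variants[is_snv, , drop = FALSE]
  ctx <- if (context_source == "column") {
    v$context
  } else {
    if (is.null(fasta_path)) abort("fasta_path required for context_source = 'fasta'")
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("the Biostrings package is required for FASTA context lookup")
    }
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    names(genome) <- sub("^chr", "", names(genome))
    vapply(seq_len(nrow(v)), function(i) {
      chr <- v$chromosome[i]
      if (!chr %in% names(genome)) return(NA_character_)
      as.character(Biostrings::subseq(genome[[chr]],
                                      v$position[i] - 1, v$position[i] + 1))
    }, "")
  }
  mid <- substr(ctx, 2, 2)
  mismatch <- !is.na(ctx) & nchar(ctx) == 3 & mid != v$ref
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(sprintf("context middle base does not match ref allele at %s:%d",
                  v$chromosome[i], v$position[i]))
  }
  cls <- sbs96_class(v$ref, v$alt, ctx)
  if (anyNA(cls) && length(cls) > 0) {
    warn(sprintf("skipped %d SBS record(s) with unknown bases or missing context",
                 sum(is.na(cls))))
  }
  keep <- !is.na(cls)
  ids <- if (is.null(samples)) sort(unique(variants$sample_id)) else samples$sample_id
  types <- sbs96_types()
  cat_m <- matrix(0L, nrow = length(ids), ncol = 96, dimnames = list(ids, types))
  if (any(keep)) {
    tab <- table(factor(v$sample_id[keep], levels = ids),
                 factor(cls[keep], levels = types))
    cat_m[] <- as.integer(tab)
  }
  cat_m
}

normalize_signatures <- function(W, H = NULL) {
  cs <- colSums(W)
  cs[cs == 0] <- 1
  W <- sweep(W, 2, cs, "/")
  if (is.null(H)) return(W)
  list(W = W, H = sweep(H, 1, cs, "*"))
}

fit_nmf_replicate <- function(V, k, resample, max_iter, tol) {
  Vr <- if (resample == "poisson") {
    matrix(rpois(length(V), lambda = V), nrow = nrow(V))
  } else V
  W0 <- matrix(runif(nrow(V) * k, 0.1, 1), nrow = nrow(V))
  H0 <- matrix(runif(k * ncol(V), 0.1, 1), nrow = k)
  fit <- .nmf_kl_cpp(Vr, W0, H0, as.integer(max_iter), tol)
  normalize_signatures(fit$W)
}

cosine_dist_matrix <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  S <- crossprod(sweep(M, 2, nrm, "/"))
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Extract de novo mutational signatures by NMF with stability selection
#'
#' For each candidate signature count `k`, fits `n_replicates` NMF models
#' (Kullback-Leibler objective, multiplicative updates) to Poisson-resampled
#' copies of the catalog from distinct random starts, pools the replicate
#' signatures, clusters them into `k` groups by cosine distance (k-medoids),
#' and scores the solution by cluster stability (mean silhouette; for
#' `k = 1`, mean cosine similarity to the medoid) and mean per-sample cosine
#' reconstruction distance. The consensus signatures are the cluster
#' medoids; exposures are refit per sample by non-negative least squares.
#' The selected `k` is the largest candidate whose stability reaches
#' `stability_floor`; if none qualifies, the candidate with the highest
#' stability (ties toward lower reconstruction error) is used.
#'
#' @param catalog Sample-by-96 count matrix from [build_catalog()].
#' @param k_min,k_max Candidate range of signature counts (defaults 1..10;
#'   capped at the number of samples).
#' @param n_replicates Resampling replicates per candidate (>= 2,
#'   default 20).
#' @param resample `"poisson"` (default) or `"none"`.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @param stability_floor Minimum stability for a candidate to be selectable
#'   (default 0.8).
#' @param max_iter,tol NMF convergence controls.
#' @return Object of class `signature_model`: `k`, `W` (96 x k, unit column
#'   sums), `H` (k x samples exposures in mutation counts), `diagnostics`
#'   tibble (`k`, `stability`, `reconstruction_error`), `models` (per-k
#'   consensus fits), `seed`, `n_replicates`.
#' @export
extract_signatures <- function(catalog, k_min = 1, k_max = 10,
                               n_replicates = 20,
                               resample = c("poisson", "none"), seed = 1L,
                               stability_floor = 0.8, max_iter = 10000,
                               tol = 1e-8) {
  resample <- match.arg(resample)
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  if (all(catalog == 0)) abort("catalog is all zero")
  V <- t(catalog)                       # 96 x samples
  k_max <- min(k_max, ncol(V))
  ks <- k_min:k_max
  set.seed(seed)
  models <- vector("list", length(ks))
  diagnostics <- tibble(k = ks, stability = NA_real_,
                        reconstruction_error = NA_real_)
  nonzero <- colSums(V) > 0
  for (i in seq_along(ks)) {
    k <- ks[i]
    reps <- lapply(seq_len(n_replicates), function(r) {
      fit_nmf_replicate(V, k, resample, max_iter, tol)
    })
    pool <- do.call(cbind, reps)        # 96 x (k * n_replicates)
    D <- cosine_dist_matrix(pool)
    if (k == 1) {
      med_idx <- which.min(rowSums(D))
      stability <- mean(1 - D[med_idx, ])
      medoids <- pool[, med_idx, drop = FALSE]
    } else {
      pm <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                         pamonce = 5)
      sil <- cluster::silhouette(pm)
      stability <- mean(sil[, "sil_width"])
      medoids <- pool[, pm$id.med, drop = FALSE]
    }
    W <- normalize_signatures(medoids)
    dimnames(W) <- list(rownames(V), paste0("Signature96-", LETTERS[seq_len(k)]))
    H <- vapply(seq_len(ncol(V)), function(j) nnls(W, V[, j]), numeric(k))
    H <- matrix(H, nrow = k,
                dimnames = list(colnames(W), colnames(V)))
    recon <- W %*% H
    recon_err <- mean(vapply(which(nonzero), function(j) {
      if (sum(recon[, j]) == 0) return(1)
      1 - cosine_similarity(V[, j], recon[, j])
    }, 0))
    diagnostics$stability[i] <- stability
    diagnostics$reconstruction_error[i] <- recon_err
    models[[i]] <- list(k = k, W = W, H = H)
  }
  eligible <- which(diagnostics$stability >= stability_floor)
  sel <- if (length(eligible) > 0) {
    max(eligible)
  } else {
    order(-diagnostics$stability, diagnostics$reconstruction_error)[1]
  }
  structure(list(
    k = ks[sel], W = models[[sel]]$W, H = models[[sel]]$H,
    diagnostics = diagnostics, models = models, seed = seed,
    n_replicates = n_replicates, stability_floor = stability_floor
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> k = %d (%d samples, %d replicates)\n",
              x$k, ncol(x$H), x$n_replicates))
  print(x$diagnostics)
  invisible(x)
}

#' Tidy exposures of a signature model
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return Long tibble `sample_id`, `signature`, `exposure` (mutation counts
#'   attributed).
#' @export
tidy.signature_model <- function(x, ...) {
  as_tibble(as.data.frame(t(x$H)), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "signature",
                        values_to = "exposure")
}

#' One-row summary of a signature model
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return One-row tibble: selected `k`, its stability and reconstruction
#'   error, sample count, and total attributed mutations.
#' @export
glance.signature_model <- function(x, ...) {
  d <- x$diagnostics[x$diagnostics$k == x$k, ]
  tibble(k = x$k, stability = d$stability,
         reconstruction_error = d$reconstruction_error,
         n_samples = ncol(x$H), total_exposure = sum(x$H))
}

#' Decompose de novo signatures onto reference spectra
#'
#' Each consensus signature is decomposed by non-negative least squares onto
#' the reference matrix; coefficients are renormalized to percentage
#' contributions (summing to 100). The assigned reference name is the
#' highest contributor; the best single-reference cosine similarity is also
#' reported.
#'
#' @param model A `signature_model` (or a bare 96 x k matrix).
#' @param reference 96 x S reference spectra matrix (see
#'   [read_signature_reference()]).
#' @return Tibble: one row per (signature, reference) with
#'   `contribution_pct`, plus per-signature `assigned_reference` and
#'   `best_cosine`.
#' @export
decompose_to_reference <- function(model, reference) {
  W <- if (inherits(model, "signature_model")) model$W else model
  if (nrow(W) != nrow(reference)) {
    abort("signature and reference matrices must have the same number of rows")
  }
  purrr::map_dfr(seq_len(ncol(W)), function(i) {
    coefs <- nnls(reference, W[, i])
    if (sum(coefs) == 0) coefs <- rep(1 / length(coefs), length(coefs))
    pct <- 100 * coefs / sum(coefs)
    cosines <- vapply(seq_len(ncol(reference)),
                      function(j) cosine_similarity(W[, i], reference[, j]), 0)
    assigned <- colnames(reference)[which.max(pct)]
    tibble(
      signature = colnames(W)[i] %||% paste0("Signature96-", LETTERS[i]),
      reference = colnames(reference),
      contribution_pct = pct,
      assigned_reference = assigned,
      best_cosine = max(cosines)
    )
  })
}

#' Compare signature exposures between cohorts
#'
#' Per signature, a two-sided Mann-Whitney test of per-sample exposures
#' between the two cohorts, reported with per-cohort medians and raw
#' p-values (significance at `p < alpha` without multiplicity adjustment, as
#' is conventional for a small fixed set of signatures).
#'
#' @param model A `signature_model`.
#' @param samples Sample tibble covering all catalog samples.
#' @param exposure_mode `"counts"` (default) or `"proportion"` (per-sample
#'   exposures normalized to sum to 1).
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param cohort_order Optional cohort ordering.
#' @return Tibble: `signature`, `median_1`, `median_2`, `p`, `significant`,
#'   `higher_cohort`.
#' @export
compare_exposures <- function(model, samples,
                              exposure_mode = c("counts", "proportion"),
                              alpha = 0.05, cohort_order = NULL) {
  exposure_mode <- match.arg(exposure_mode)
  cohorts <- cohort_pair(samples, cohort_order)
  H <- model$H
  missing_lab <- setdiff(colnames(H), samples$sample_id)
  if (length(missing_lab) > 0) {
    abort(sprintf("samples without cohort labels: %s",
                  paste(missing_lab, collapse = ", ")))
  }
  if (exposure_mode == "proportion") {
    tot <- colSums(H)
    tot[tot == 0] <- 1
    H <- sweep(H, 2, tot, "/")
  }
  lab <- samples$cohort[match(colnames(H), samples$sample_id)]
  purrr::map_dfr(rownames(H), function(sig) {
    x <- H[sig, lab == cohorts[1]]
    y <- H[sig, lab == cohorts[2]]
    p <- mann_whitney_u(x, y, mode = "normal")$p_value
    tibble(signature = sig, median_1 = median(x), median_2 = median(y),
           p = p, significant = p < alpha,
           higher_cohort = ifelse(median(x) > median(y), cohorts[1],
                                  ifelse(median(y) > median(x), cohorts[2],
                                         NA_character_)))
  })
}
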