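# SBS96 catalog construction, NMF extraction, reference decomposition and
# exposure comparison.

test_that("SBS96 classification is pyrimidine-centered with reverse
           complementing", {
  v <- make_variants(3,
    ref = c("C", "G", "A"), alt = c("T", "A", "G"),
    context = c("ACA", "TGC", "CAT"),
    sample_id = c("S1", "S1", "S2")
  )
  cat_m <- build_catalog(v)
  expect_equal(cat_m["S1", "A[C>T]A"], 1L)
  # G>A in context TGC -> reverse complement -> G[C>T]A
  expect_equal(cat_m["S1", "G[C>T]A"], 1L)
  # A>G in CAT -> complement to T>C, revcomp(CAT)=ATG -> A[T>C]G
  expect_equal(cat_m["S2", "A[T>C]G"], 1L)
  expect_equal(sum(cat_m), 3)
})

test_that("catalog conserves SBS counts, skips indels, and validates the
           context middle base", {
  v <- make_variants(4,
    ref = c("C", "AC", "C", "C"), alt = c("T", "A", "G", "A"),
    context = c("ACA", NA, "TCG", "GCT")
  )
  expect_message(cat_m <- build_catalog(v), "non-SBS")
  expect_equal(sum(cat_m), 3)                 # row sums = retained SBS count
  bad <- make_variants(1, ref = "C", context = "AAA")
  expect_error(build_catalog(bad), "middle base")
  # roster samples without SBS records appear as zero rows
  samples <- make_samples(1, 1)
  v2 <- make_variants(1, sample_id = "A01")
  cat2 <- suppressMessages(build_catalog(v2, samples))
  expect_equal(rownames(cat2), samples$sample_id)
  expect_equal(sum(cat2["B01", ]), 0)
})

test_that("FASTA context lookup matches the precomputed context column", {
  skip_if_not_installed("Biostrings")
  set.seed(31)
  seq_chars <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  pos <- seq(10, 590, by = 7)[1:40]
  ref <- vapply(pos, function(p) seq_chars[p], "")
  ok <- ref %in% c("C", "T", "A", "G")
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  ctx <- vapply(pos, function(p) paste(seq_chars[(p - 1):(p + 1)],
                                       collapse = ""), "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">1 test", paste(seq_chars, collapse = "")), fa)
  v <- make_variants(length(pos), position = pos, ref = ref, alt = alt,
                     context = ctx)
  from_col <- build_catalog(v, context_source = "column")
  from_fa <- build_catalog(v, context_source = "fasta", fasta_path = fa)
  expect_equal(from_fa, from_col)
})

test_that("a single-spectrum catalog selects k = 1 and recovers the spectrum", {
  study <- make_signature_study(seed = 11, n_samples = 60, n_mut = 120)
  # collapse to one true spectrum
  set.seed(11)
  S1 <- study$spectra[, 1]
  catalog <- t(vapply(1:60, function(i) as.integer(rmultinom(1, 120, S1)),
                      integer(96)))
  dimnames(catalog) <- list(sprintf("s%02d", 1:60), sbs96_types())
  m <- extract_signatures(catalog, k_min = 1, k_max = 3, n_replicates = 6,
                          seed = 2, max_iter = 1000, tol = 1e-6)
  expect_equal(m$k, 1)
  expect_gte(cosine_similarity(m$W[, 1], S1), 0.99)
  expect_true(all(abs(colSums(m$W) - 1) < 1e-9))
  expect_true(all(m$H >= 0))
})

test_that("extraction is bit-identical under a repeated seed", {
  study <- make_signature_study(seed = 4, n_samples = 40, n_mut = 100)
  m1 <- extract_signatures(study$catalog, 1, 3, n_replicates = 4, seed = 9,
                           max_iter = 500, tol = 1e-6)
  m2 <- extract_signatures(study$catalog, 1, 3, n_replicates = 4, seed = 9,
                           max_iter = 500, tol = 1e-6)
  expect_identical(m1$diagnostics, m2$diagnostics)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$H, m2$H)
  expect_error(extract_signatures(study$catalog * 0L, 1, 2, 4), "zero")
})

test_that("reference decomposition recovers exact mixtures and argmax naming", {
  set.seed(41)
  ref <- matrix(rgamma(96 * 4, 0.3), 96)
  ref <- sweep(ref, 2, colSums(ref), "/")
  rownames(ref) <- sbs96_types()
  colnames(ref) <- paste0("SBSref", 1:4)
  W <- cbind(ref[, 3], 0.7 * ref[, 1] + 0.3 * ref[, 2])
  colnames(W) <- c("sigX", "sigY")
  d <- decompose_to_reference(W, ref)
  x <- d[d$signature == "sigX", ]
  expect_equal(x$contribution_pct[x$reference == "SBSref3"], 100,
               tolerance = 1e-6)
  expect_equal(unique(x$assigned_reference), "SBSref3")
  expect_equal(unique(x$best_cosine), 1, tolerance = 1e-12)
  y <- d[d$signature == "sigY", ]
  expect_equal(y$contribution_pct[y$reference == "SBSref1"], 70,
               tolerance = 1e-6)
  expect_equal(y$contribution_pct[y$reference == "SBSref2"], 30,
               tolerance = 1e-6)
  expect_equal(sum(y$contribution_pct), 100, tolerance = 1e-6)
  expect_error(decompose_to_reference(W[1:90, ], ref), "same number of rows")
})

test_that("exposure comparison detects planted shifts and is symmetric under
           label swap", {
  set.seed(51)
  H <- rbind(sig1 = c(rgamma(30, 2, scale = 5), rgamma(30, 2, scale = 15)),
             sig2 = rgamma(60, 2, scale = 10))
  colnames(H) <- sprintf("s%02d", 1:60)
  model <- structure(list(H = H, k = 2), class = "signature_model")
  samples <- tibble::tibble(sample_id = colnames(H),
                            cohort = rep(c("A", "B"), each = 30))
  et <- compare_exposures(model, samples)
  expect_true(et$significant[et$signature == "sig1"])
  expect_equal(et$higher_cohort[et$signature == "sig1"], "B")
  swapped <- samples
  swapped$cohort <- ifelse(samples$cohort == "A", "B", "A")
  et2 <- compare_exposures(model, swapped)
  expect_equal(et$p, et2$p, tolerance = 1e-12)
  # proportion mode normalizes per sample
  etp <- compare_exposures(model, samples, exposure_mode = "proportion")
  expect_equal(nrow(etp), 2)
  expect_error(compare_exposures(model, samples[-1, ]), "without cohort")
})

test_that("tidy and glance views of a signature model are consistent", {
  study <- make_signature_study(seed = 8, n_samples = 30, n_mut = 80)
  m <- extract_signatures(study$catalog, 2, 3, n_replicates = 3, seed = 3,
                          max_iter = 300, tol = 1e-5)
  td <- tidy(m)
  expect_setequal(unique(td$sample_id), rownames(study$catalog))
  expect_equal(nrow(td), m$k * 30)
  gl <- glance(m)
  expect_equal(gl$k, m$k)
  expect_equal(gl$total_exposure, sum(m$H))
})
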