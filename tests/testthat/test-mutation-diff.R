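# Mutation matrix construction, per-gene frequency tests, bootstrap
# stability.

test_that("mutation matrix collapses multi-hits, keeps all-zero columns and
           rejects off-roster samples", {
  samples <- make_samples(2, 2)
  v <- make_variants(3, sample_id = c("A01", "A01", "B01"),
                     gene = c("G001", "G001", "G002"))
  mm <- build_mutation_matrix(v, samples, panel = c("G001", "G002", "G003"))
  expect_equal(dim(mm$indicator), c(3, 4))
  expect_equal(mm$indicator["G001", "A01"], 1L)       # two hits collapse to 1
  expect_equal(sum(mm$indicator[, "A02"]), 0L)        # unmutated roster sample
  expect_equal(sum(mm$indicator["G003", ]), 0L)
  bad <- make_variants(1, sample_id = "GHOST")
  expect_error(build_mutation_matrix(bad, samples, "G001"), "GHOST")
})

test_that("mutation matrix holds the full 17 + 689 roster as columns", {
  samples <- make_samples(17, 689)
  mm <- build_mutation_matrix(make_variants(1, sample_id = "A01"),
                              samples, panel = "G001")
  expect_equal(ncol(mm$indicator), 706)
})

test_that("per-gene tests reproduce the high-frequency worked example and
           keep cohort-size margins", {
  # 4/17 vs 17/689: frequencies 23.53% and 2.47%, OR 2688/221
  mm <- make_mm(counts1 = c(4, 2, 0), counts2 = c(17, 80, 0),
                n1 = 17, n2 = 689)
  res <- test_gene_frequencies(mm)
  g1 <- res[res$gene == "G001", ]
  expect_equal(round(100 * g1$freq_1, 2), 23.53)
  expect_equal(round(100 * g1$freq_2, 2), 2.47)
  expect_equal(g1$odds_ratio, 2688 / 221, tolerance = 1e-12)
  expect_equal(g1$enriched_cohort, "A")
  # margins equal cohort sizes for every gene
  expect_true(all(res$n_1 == 17 & res$n_2 == 689))
  # the never-mutated gene is excluded from the BH family
  expect_false(res$tested[res$gene == "G003"])
  expect_true(is.na(res$q[res$gene == "G003"]))
  expect_equal(sum(res$tested), 2)
})

test_that("equal-frequency genes are not significant and q >= p", {
  mm <- make_mm(counts1 = c(5, 3), counts2 = c(50, 30), n1 = 10, n2 = 100)
  res <- test_gene_frequencies(mm)
  expect_false(any(res$significant))
  expect_true(all(res$q >= res$p - 1e-15, na.rm = TRUE))
  single <- structure(list(indicator = mm$indicator[, 1:10, drop = FALSE],
                           samples = mm$samples[1:10, ]),
                      class = "mutation_matrix")
  expect_error(test_gene_frequencies(single), "2 cohorts")
})

test_that("bootstrap log-OR is seeded-reproducible with sensible consistency", {
  set.seed(99)
  mm_strong <- make_mm(8, 1, n1 = 10, n2 = 100)
  b1 <- bootstrap_log_or(mm_strong, "G001", n_resamples = 2000, seed = 5)
  b2 <- bootstrap_log_or(mm_strong, "G001", n_resamples = 2000, seed = 5)
  expect_identical(b1, b2)
  expect_gte(b1$consistency, 0.99)
  mm_null <- make_mm(5, 50, n1 = 10, n2 = 100)
  b0 <- bootstrap_log_or(mm_null, "G001", n_resamples = 4000, seed = 6)
  expect_lt(abs(b0$consistency - 0.5), 0.1)
  expect_error(bootstrap_log_or(mm_null, "G001", n_resamples = 0), ">= 1")
  expect_error(bootstrap_log_or(mm_null, "NOPE"), "NOPE")
})

test_that("Haldane-Anscombe smoothing applies only to zero-cell tables", {
  mm <- make_mm(c(4, 3), c(17, 0), n1 = 17, n2 = 689)
  b <- bootstrap_log_or(mm, "G001", n_resamples = 10, seed = 1)
  expect_equal(b$log_or, log(2688 / 221))            # untouched, no zero cell
  bz <- bootstrap_log_or(mm, "G002", n_resamples = 10, seed = 1)
  expect_equal(bz$log_or,
               log((3.5 * 689.5) / (14.5 * 0.5)))    # +0.5 on all four cells
})

test_that("oncotable joins multi-hit classifications deterministically", {
  samples <- make_samples(1, 1)
  v <- make_variants(3, sample_id = c("A01", "A01", "B01"),
                     gene = c("G001", "G001", "G001"),
                     classification = c("nonsense", "missense", "missense"))
  ot <- oncotable(v, samples, panel = c("G001", "G002"))
  expect_equal(nrow(ot), 4)
  expect_equal(ot$classes[ot$gene == "G001" & ot$sample_id == "A01"],
               "missense;nonsense")
  expect_equal(ot$classes[ot$gene == "G002" & ot$sample_id == "B01"], "")
})
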