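# Segment-to-gene status logic, valid-sample denominators, arm collapse,
# burden identities, and arm-level testing.

test_that("status assignment follows the conflict rules in both modes", {
  genes <- tibble::tibble(gene = "G001", chromosome = "1",
                          start = 100, end = 200)
  samples <- tibble::tibble(sample_id = "S1", cohort = "A")
  seg <- function(states, ivs) {
    tibble::tibble(sample_id = "S1", chromosome = "1",
                   start = sapply(ivs, `[`, 1), end = sapply(ivs, `[`, 2),
                   state = states)
  }
  # gain + loss overlap -> invalid in both modes
  s <- seg(c("gain", "loss"), list(c(50, 150), c(150, 300)))
  expect_equal(assign_gene_status(s, genes, samples)$status, "invalid")
  expect_equal(assign_gene_status(s, genes, samples, "strict")$status,
               "invalid")
  # gain + neutral -> gain by default, invalid in strict mode
  s <- seg(c("gain", "neutral"), list(c(50, 150), c(150, 300)))
  expect_equal(assign_gene_status(s, genes, samples)$status, "gain")
  expect_equal(assign_gene_status(s, genes, samples, "strict")$status,
               "invalid")
  # only neutral -> neutral; no overlap -> missing
  s <- seg("neutral", list(c(0, 500)))
  expect_equal(assign_gene_status(s, genes, samples)$status, "neutral")
  s <- seg("gain", list(c(300, 400)))
  expect_equal(assign_gene_status(s, genes, samples)$status, "missing")
  # half-open intersection: a segment ending exactly at gene start is no hit
  s <- seg("gain", list(c(0, 100)))
  expect_equal(assign_gene_status(s, genes, samples)$status, "missing")
  expect_error(assign_gene_status(s, genes, samples, "bogus"), "arg")
})

test_that("CNV frequencies use valid samples as denominators and flag
           infinite odds ratios", {
  ann <- make_annotation(1)
  samples <- make_samples(12, 10)
  # cohort A: 3 gains, 7 neutral, 2 invalid -> freq 3/10 among valid
  st_a <- tibble::tibble(
    sample_id = samples$sample_id[1:12], gene = "G001",
    status = c(rep("gain", 3), rep("neutral", 7), rep("invalid", 2))
  )
  st_b <- tibble::tibble(
    sample_id = samples$sample_id[13:22], gene = "G001",
    status = rep("neutral", 10)
  )
  tab <- dplyr::bind_rows(st_a, st_b)
  res <- test_cnv_frequencies(tab, samples, "gain")
  expect_equal(res$n_valid_1, 10)
  expect_equal(res$freq_1, 0.3)
  expect_equal(res$freq_2, 0)
  expect_identical(res$odds_ratio, Inf)
  expect_true(res$or_infinite)
  # change counts gains and losses together
  tab$status[tab$status == "neutral"][1] <- "loss"
  chg <- test_cnv_frequencies(tab, samples, "change")
  expect_equal(chg$n_event_1, 4)
  expect_error(test_cnv_frequencies(tab, samples, "amp"), "arg")
})

test_that("genes lacking valid samples in a cohort are skipped with a reason", {
  samples <- make_samples(2, 2)
  tab <- tidyr::expand_grid(sample_id = samples$sample_id, gene = "G001") |>
    dplyr::mutate(status = c("gain", "neutral", "missing", "missing"))
  res <- test_cnv_frequencies(tab, samples, "gain")
  expect_false(res$tested)
  expect_match(res$skip_reason, "no valid sample")
})

test_that("arm collapse flags an arm on any single gene event and burdens are
           row sums", {
  ann <- make_annotation(8)   # genes alternate chromosomes 1,2 and arms
  samples <- make_samples(1, 1)
  tab <- tidyr::expand_grid(sample_id = samples$sample_id,
                            gene = ann$genes$gene) |>
    dplyr::mutate(status = "neutral")
  # one gene on 1p gained, one on 2q lost for sample A01
  g1p <- ann$genes$gene[ann$genes$chromosome == "1" &
                          ann$genes$end <= 10000][1]
  g2q <- ann$genes$gene[ann$genes$chromosome == "2" &
                          ann$genes$start >= 10000][1]
  tab$status[tab$sample_id == "A01" & tab$gene == g1p] <- "gain"
  tab$status[tab$sample_id == "A01" & tab$gene == g2q] <- "loss"
  arm <- collapse_to_arms(tab, ann$genes, ann$arms)
  fl <- arm$flags[arm$flags$sample_id == "A01", ]
  expect_true(fl$gained[fl$arm_label == "1p"])
  expect_true(fl$lost[fl$arm_label == "2q"])
  bu <- arm$burden[arm$burden$sample_id == "A01", ]
  expect_equal(bu$n_arms_gained, 1)
  expect_equal(bu$n_arms_lost, 1)
  b0 <- arm$burden[arm$burden$sample_id == "B01", ]
  expect_equal(b0$n_arms_gained + b0$n_arms_lost, 0)
})

test_that("burden equals the count of flagged arms on random status tables", {
  set.seed(61)
  ann <- make_annotation(12)
  samples <- make_samples(4, 4)
  for (i in 1:5) {
    tab <- tidyr::expand_grid(sample_id = samples$sample_id,
                              gene = ann$genes$gene) |>
      dplyr::mutate(status = sample(c("gain", "loss", "neutral", "invalid",
                                      "missing"),
                                    dplyr::n(), replace = TRUE))
    arm <- collapse_to_arms(tab, ann$genes, ann$arms)
    chk <- arm$flags |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(g = sum(gained), l = sum(lost)) |>
      dplyr::left_join(arm$burden, by = "sample_id")
    expect_equal(chk$g, chk$n_arms_gained)
    expect_equal(chk$l, chk$n_arms_lost)
  }
})

test_that("a gene with its midpoint outside every arm is left out with a
           warning", {
  ann <- make_annotation(2)
  genes <- ann$genes
  genes$start[1] <- 50000; genes$end[1] <- 50010   # beyond both arm ends
  tab <- tibble::tibble(sample_id = "A01", gene = genes$gene,
                        status = "gain")
  expect_warning(arm <- collapse_to_arms(tab, genes, ann$arms), "unassigned")
})

test_that("the fully separated arm attains the smallest p and identical
           cohorts give null burden comparisons", {
  ann <- make_annotation(8)
  samples <- make_samples(6, 6)
  tab <- tidyr::expand_grid(sample_id = samples$sample_id,
                            gene = ann$genes$gene) |>
    dplyr::mutate(status = "neutral")
  # arm 1p gained in every cohort-A sample, never in B; arm 1q in one sample
  genes_1p <- ann$genes$gene[ann$genes$chromosome == "1" &
                               ann$genes$end <= 10000]
  tab$status[tab$gene %in% genes_1p &
               tab$sample_id %in% samples$sample_id[1:6]] <- "gain"
  g1q <- ann$genes$gene[ann$genes$chromosome == "1" &
                          ann$genes$start >= 10000][1]
  tab$status[tab$gene == g1q & tab$sample_id == "A01"] <- "gain"
  arm <- collapse_to_arms(tab, ann$genes, ann$arms)
  at <- test_arm_frequencies(arm, samples)
  gains <- at[at$event == "gain", ]
  expect_equal(gains$arm_label[which.min(gains$p)], "1p")
  expect_equal(gains$enriched_cohort[gains$arm_label == "1p"], "A")
  # identical cohorts: all q near 1
  tab2 <- tidyr::expand_grid(sample_id = samples$sample_id,
                             gene = ann$genes$gene) |>
    dplyr::mutate(status = rep(c("gain", "neutral"),
                               length.out = dplyr::n()))
  suppressWarnings({
    arm2 <- collapse_to_arms(tab2, ann$genes, ann$arms)
    at2 <- test_arm_frequencies(arm2, samples)
  })
  expect_true(all(at2$q > 0.9))
  bu2 <- compare_burden(arm2, samples)
  expect_true(all(bu2$p == 1))
})
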