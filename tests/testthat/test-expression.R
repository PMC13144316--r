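# Rank-based differential expression: filter boundaries, tie handling, the
# monotone-invariance property at the heart of the cross-platform design.

make_expr <- function(values, samples) {
  m <- matrix(values, nrow = length(values) / nrow(samples), byrow = FALSE)
  dimnames(m) <- list(sprintf("G%02d", seq_len(nrow(m))), samples$sample_id)
  m
}

test_that("low-expression filter keeps genes adequately expressed in at
           least one cohort (strict <)", {
  samples <- make_samples(2, 2)
  m <- rbind(
    G1 = c(30, 30, 3, 3),      # high in A only -> kept
    G2 = c(3, 3, 4, 4),        # low in both -> dropped
    G3 = c(9.99, 9.99, 10, 10) # exactly 10 in B -> kept (strict <)
  )
  colnames(m) <- samples$sample_id
  out <- filter_low_expression(m, samples)
  expect_setequal(rownames(out), c("G1", "G3"))
  pooled <- filter_low_expression(m, samples, mode = "pooled")
  expect_equal(rownames(pooled), "G1")   # pooled mean 16.5; others below 10
  expect_error(filter_low_expression(m, samples, mode = "nope"), "arg")
})

test_that("rank transform averages ties per sample and is scale-free", {
  m <- matrix(c(5, 5, 10), 3, 1, dimnames = list(c("a", "b", "c"), "S1"))
  expect_equal(unname(rank_transform(m)[, 1]), c(1.5, 1.5, 3))
  all_eq <- matrix(7, 4, 1, dimnames = list(letters[1:4], "S1"))
  expect_equal(unname(rank_transform(all_eq)[, 1]), rep(2.5, 4))
  set.seed(3)
  m2 <- matrix(rlnorm(50), 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  expect_equal(rank_transform(m2^3 * 7), rank_transform(m2))
})

test_that("the worked fold-change example and DEG thresholds hold", {
  samples <- make_samples(3, 3)
  # gene with means 31 vs 7 -> log2((31+1)/(7+1)) = 2 exactly; G2 sits at a
  # constant within-sample rank so its distributions are identical
  m <- rbind(G1 = c(31, 31, 31, 7, 7, 7),
             G2 = rep(50, 6),
             G3 = rep(100, 6))
  colnames(m) <- samples$sample_id
  ranks <- rank_transform(m)
  res <- test_differential_expression(ranks, m, samples)
  expect_equal(res$log2_fold_change[res$gene == "G1"], 2)
  g2 <- res[res$gene == "G2", ]
  expect_equal(g2$p, 1)
  expect_false(g2$deg)
  bad <- ranks; rownames(bad) <- rev(rownames(bad))
  expect_error(test_differential_expression(bad, m, samples), "share")
})

test_that("U-test p-values are invariant under per-sample monotone
           distortions while log2FC is not", {
  set.seed(17)
  samples <- make_samples(8, 12)
  n_genes <- 60
  m <- matrix(rlnorm(n_genes * 20, log(50), 1), n_genes, 20,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              samples$sample_id))
  m[1:5, 1:8] <- m[1:5, 1:8] * 6      # a few shifted genes
  ranks <- rank_transform(m)
  base <- test_differential_expression(ranks, m, samples)
  # strictly monotone, sample-specific distortions (power and scale)
  distorted <- m
  for (j in seq_len(ncol(m))) {
    distorted[, j] <- runif(1, 0.5, 2) * m[, j]^runif(1, 0.6, 1.4)
  }
  res_d <- test_differential_expression(rank_transform(distorted), distorted,
                                        samples)
  ord <- match(base$gene, res_d$gene)
  expect_equal(base$p, res_d$p[ord], tolerance = 1e-12)
  expect_gt(max(abs(base$log2_fold_change - res_d$log2_fold_change[ord])),
            0.1)
})

test_that("planted DEGs are recovered and the up/down partition is complete", {
  set.seed(29)
  samples <- make_samples(17, 40)
  n_genes <- 300
  mu <- rlnorm(n_genes, log(100), 1)
  m <- matrix(rlnorm(n_genes * 57, 0, 0.5), n_genes) * mu
  dimnames(m) <- list(sprintf("g%03d", 1:n_genes), samples$sample_id)
  up_a <- sprintf("g%03d", 1:15)
  up_b <- sprintf("g%03d", 16:25)
  m[up_a, 1:17] <- m[up_a, 1:17] * 8
  m[up_b, 18:57] <- m[up_b, 18:57] * 8
  res <- run_expression_diff(m, samples)
  found <- res$gene[res$deg]
  expect_gte(mean(c(up_a, up_b) %in% found), 0.9)
  expect_equal(sum(res$deg & res$direction == "up_1") +
                 sum(res$deg & res$direction == "up_2"), sum(res$deg))
  expect_true(all(res$direction[res$gene %in% up_a & res$deg] == "up_1"))
})
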