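# Statistical primitives against independent oracles: base-R reference
# implementations, exhaustive enumeration, and closed forms.

# enumeration oracle for the two-sided Fisher p (probability-mass rule),
# written directly against dhyper, independent of the implementation
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c
  support <- max(0, c1 - (c + d)):min(r1, c1)
  probs <- stats::dhyper(support, c1, b + d, r1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher two-sided p matches enumeration and base R on random tables", {
  set.seed(101)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(1, 5, 20), 1))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    got <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    if (sum(cells) > 0 && all(colSums(matrix(cells, 2)) > 0)) {
      ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
      expect_equal(got$p_value, ft$p.value, tolerance = 1e-7)
    }
  }
})

test_that("Fisher handles balanced, empty-margin and the ARID1B-style table", {
  bal <- fisher_exact_two_sided(5, 5, 5, 5)
  expect_equal(bal$p_value, 1)
  expect_equal(bal$odds_ratio, 1)
  expect_warning(z <- fisher_exact_two_sided(0, 17, 0, 689),
                 "all-zero margin")
  expect_equal(z$p_value, 1)
  expect_true(is.na(z$odds_ratio))
  # 4/17 vs 17/689 mutated: cross-product odds ratio 2688/221
  ar <- fisher_exact_two_sided(4, 13, 17, 672)
  expect_equal(ar$odds_ratio, 2688 / 221)
  expect_equal(ar$p_value, fisher_oracle(4, 13, 17, 672), tolerance = 1e-12)
  inf <- fisher_exact_two_sided(3, 0, 1, 5)
  expect_identical(inf$odds_ratio, Inf)
})

test_that("BH adjustment matches p.adjust and the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Mann-Whitney exact mode equals full enumeration", {
  # independent enumeration over all labelings
  mw_oracle <- function(x, y) {
    n1 <- length(x); N <- n1 + length(y)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  }
  expect_equal(mann_whitney_u(1:3, 4:6)$p_value, 0.1)
  set.seed(33)
  for (i in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1000, n1 + n2)       # tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 mw_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney degenerate and tied inputs give p = 1 and the normal
           branch matches wilcox.test", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(20, 0.5)
    got <- mann_whitney_u(x, y, mode = "normal")$p_value
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # label symmetry of the alias
  x <- rnorm(8); y <- rnorm(11)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(y, x)$p_value, tolerance = 1e-12)
})

test_that("hypergeometric upper tail matches phyper, brute force and sums to 1", {
  expect_equal(hypergeom_upper_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  brute <- function(N, K, n, k) {
    sum(vapply(k:min(n, K), function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, 0))
  }
  expect_equal(hypergeom_upper_tail(10, 5, 5, 3), brute(10, 5, 5, 3),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:100) {
    N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- if (lo == hi) lo else sample(seq(lo, hi), 1)
    got <- hypergeom_upper_tail(N, K, n, k)
    expect_equal(got, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(hypergeom_upper_tail(N, K, n, lo), 1)
    # complement identity: P(X >= k) + P(X <= k-1) = 1
    if (k > lo) {
      expect_equal(got + stats::phyper(k - 1, K, N - K, n), 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_upper_tail(10, 11, 5, 3), "K <= N")
})

test_that("cosine similarity on identities, orthogonal and worked vectors", {
  v <- runif(10)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("NNLS recovers exact mixtures and beats clipped least squares", {
  set.seed(9)
  A <- matrix(runif(96 * 5), 96)
  A <- sweep(A, 2, colSums(A), "/")
  x <- nnls(A, 0.7 * A[, 1] + 0.3 * A[, 2])
  expect_equal(x, c(0.7, 0.3, 0, 0, 0), tolerance = 1e-8)
  expect_equal(nnls(A, A[, 4]), c(0, 0, 0, 1, 0), tolerance = 1e-8)
  for (i in 1:20) {
    B <- matrix(runif(30 * 4), 30)
    b <- runif(30) - 0.3
    x <- nnls(B, b)
    expect_true(all(x >= 0))
    obj <- sum((B %*% x - b)^2)
    ols_clip <- pmax(qr.solve(B, b), 0)
    expect_lte(obj, sum((B %*% ols_clip - b)^2) + 1e-10)
    if (requireNamespace("pracma", quietly = TRUE)) {
      ref <- pracma::lsqnonneg(B, b)
      expect_equal(obj, sum((B %*% ref$x - b)^2), tolerance = 1e-8)
    }
  }
})
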