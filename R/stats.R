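# Statistical primitives. Each is self-contained and checked against an
# independent oracle (enumeration, closed form, or a second implementation)
# in the test suite.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Tests association in a 2x2 contingency table by exhaustive evaluation of
#' the conditional hypergeometric distribution. The two-sided p-value follows
#' the probability-mass convention: it sums the probabilities of all tables
#' with the same margins whose probability does not exceed that of the
#' observed table (with a small relative tolerance on the comparison to
#' absorb floating-point noise).
#'
#' The odds ratio is the unconditional cross-product ratio `(a*d)/(b*c)`:
#' `Inf` when `b*c == 0` with `a*d > 0`, and `NA` when both products are
#' zero. A table with an all-zero margin is untestable and returns `p = 1`
#' with a warning.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` events and `b`
#'   non-events in group 1, `c` events and `d` non-events in group 2.
#' @param mass_tol Relative tolerance used when comparing table probabilities
#'   to the observed table's probability.
#' @return A one-row tibble with columns `statistic` (the observed cell `a`),
#'   `p_value`, `odds_ratio`, `method`.
#' @examples
#' fisher_exact_two_sided(4, 13, 17, 672)
#' @export
fisher_exact_two_sided <- function(a, b, c, d, mass_tol = 1e-7) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("all four cell counts must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  odds_ratio <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warn("2x2 table has an all-zero margin; returning p = 1")
    p <- 1
  } else {
    p <- fisher_p(a, b, c, d, mass_tol)
  }
  tibble::new_tibble(list(
    statistic = as.numeric(a), p_value = p,
    odds_ratio = odds_ratio, method = "fisher_exact_two_sided"
  ), nrow = 1L)
}

# scalar probability-mass two-sided p; margins assumed non-degenerate
fisher_p <- function(a, b, c, d, mass_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(r1, c1)
  # log hypergeometric pmf over the support, own arithmetic via lchoose
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  p_obs <- logp[support == a]
  min(1, sum(exp(logp[logp <= p_obs + log1p(mass_tol)])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH-adjusted p-values (q-values): sort ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and return in the input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exact null distribution of the rank-sum of the first sample: enumeration of
# all C(n1+n2, n1) labelings (used only at small n)
mw_exact_p <- function(u_obs, n1, n2) {
  combs <- utils::combn(n1 + n2, n1)
  u_all <- colSums(combs) - n1 * (n1 + 1) / 2
  total <- ncol(combs)
  p_lo <- sum(u_all <= u_obs) / total
  p_hi <- sum(u_all >= u_obs) / total
  min(1, 2 * min(p_lo, p_hi))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test on two samples using joint average ranks. In `"auto"` mode
#' the exact null distribution is enumerated when `length(x) + length(y) <= 12`
#' and there are no ties; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return A one-row tibble: `statistic` (U for the `x` sample), `p_value`,
#'   `odds_ratio` (`NA`, kept for a uniform test-result shape), `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = (N <= 12 && !has_ties)
  )
  if (use_exact && has_ties) {
    abort("exact mode requires tie-free samples")
  }
  if (use_exact) {
    p <- mw_exact_p(u, n1, n2)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      cc <- min(0.5, abs(z))      # continuity correction toward the mean
      z <- (abs(z) - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  tibble::new_tibble(list(
    statistic = u, p_value = p, odds_ratio = NA_real_,
    method = paste0("mann_whitney_", if (use_exact) "exact" else "normal")
  ), nrow = 1L)
}

#' Wilcoxon rank-sum test
#'
#' Alias of [mann_whitney_u()] (identical statistic and p-value); provided
#' because arm-burden comparisons are conventionally reported under this name.
#'
#' @inheritParams mann_whitney_u
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  out <- mann_whitney_u(x, y, mode)
  out$method <- sub("mann_whitney", "wilcoxon_rank_sum", out$method)
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` is the overlap of `n` draws with a category of size
#' `K` in a universe of size `N`, summed in log space.
#'
#' @param N Universe size.
#' @param K Category size.
#' @param n Number of draws.
#' @param k Observed overlap.
#' @return Upper-tail probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N) abort("require 0 <= K <= N and 0 <= n <= N")
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (k < lo || k > hi) abort("k outside the hypergeometric support")
  support <- k:hi
  logp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Cosine similarity of two non-negative vectors
#'
#' @param u,v Non-negative numeric vectors with positive norm.
#' @return `dot(u, v) / (|u| |v|)` in \[0, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for a zero vector")
  min(1, sum(u * v) / (nu * nv))
}

#' Non-negative least squares
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the Lawson-Hanson
#' active-set algorithm. Problem sizes here are small (96 rows, a handful of
#' columns), so a plain R implementation is exact and fast.
#'
#' @param A Numeric matrix (rows >= cols typical).
#' @param b Numeric vector, `length(b) == nrow(A)`.
#' @param tol Dual-feasibility tolerance.
#' @return Non-negative coefficient vector of length `ncol(A)`.
#' @export
nnls <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  if (length(b) != nrow(A)) abort("length(b) must equal nrow(A)")
  m <- ncol(A)
  x <- numeric(m)
  passive <- logical(m)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  max_outer <- 30 * m
  while (any(!passive & w > tol) && iter < max_outer) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      Ap <- A[, P, drop = FALSE]
      s <- numeric(m)
      sol <- tryCatch(
        qr.solve(Ap, b),
        error = function(e) rep(0, length(P))
      )
      s[P] <- sol
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}
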