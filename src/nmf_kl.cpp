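#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kullback-Leibler divergence D(V || WH), ignoring zero entries of V in the
// log term (0 * log 0 := 0).
static double kl_div(const arma::mat& V, const arma::mat& WH) {
  double d = 0.0;
  const arma::uword n = V.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double v = V(i), wh = WH(i);
    if (wh < 1e-300) wh = 1e-300;
    if (v > 0.0) d += v * std::log(v / wh) - v + wh;
    else d += wh;
  }
  return d;
}

// Multiplicative-update NMF under the KL objective (Lee & Seung).
// V: m x n non-negative matrix; W0: m x k; H0: k x n starting points.
// Stops when the relative decrease of the objective over a 10-iteration
// window falls below tol, or at max_iter.
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
List nmf_kl_cpp(const arma::mat& V, const arma::mat& W0, const arma::mat& H0,
                int max_iter, double tol) {
  arma::mat W = W0, H = H0;
  const double eps = 1e-12;
  arma::mat WH = W * H;
  double obj = kl_div(V, WH), obj_prev = obj;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update: H <- H .* (W' (V ./ WH)) ./ (W' 1)
    arma::mat Q = V / arma::clamp(WH, eps, arma::datum::inf);
    arma::colvec wsum = arma::sum(W, 0).t();           // k
    H %= (W.t() * Q);
    H.each_col() /= arma::clamp(wsum, eps, arma::datum::inf);
    WH = W * H;
    // W update: W <- W .* ((V ./ WH) H') ./ (1 H')
    Q = V / arma::clamp(WH, eps, arma::datum::inf);
    arma::rowvec hsum = arma::sum(H, 1).t();           // k
    W %= (Q * H.t());
    W.each_row() /= arma::clamp(hsum, eps, arma::datum::inf);
    WH = W * H;
    if (it % 10 == 0) {
      obj = kl_div(V, WH);
      double denom = std::max(std::abs(obj_prev), 1e-300);
      if (std::abs(obj_prev - obj) / denom < tol) break;
      obj_prev = obj;
    }
  }
  obj = kl_div(V, WH);
  return List::create(_["W"] = W, _["H"] = H,
                      _["objective"] = obj, _["iterations"] = std::min(it, max_iter));
}
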