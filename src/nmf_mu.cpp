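#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF for the Frobenius objective ||X - W H||_F^2.
//
// update: 0 = alternate W and H, 1 = update W only (H fixed),
//         2 = update H only (W fixed).
// tol < 0 disables the convergence test, so exactly max_iter updates run
// (the fixed-factor cross-reconstruction procedure relies on this).
// eps guards denominators against exact zeros; it does not regularize.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                int max_iter, double tol, int update) {
  const double eps = 1e-12;
  std::vector<double> err;
  err.reserve(max_iter + 1);

  double e_prev = arma::accu(arma::square(X - W * H));
  err.push_back(e_prev);

  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    if (update == 0 || update == 2) {
      // H <- H .* (W'X) ./ (W'W H)
      H %= (W.t() * X) / (W.t() * W * H + eps);
    }
    if (update == 0 || update == 1) {
      // W <- W .* (X H') ./ (W H H')
      W %= (X * H.t()) / (W * (H * H.t()) + eps);
    }
    double e = arma::accu(arma::square(X - W * H));
    err.push_back(e);
    if (tol >= 0.0) {
      double rel = std::abs(e_prev - e) / std::max(e_prev, eps);
      if (rel < tol) { ++it; break; }
    }
    e_prev = e;
  }

  return List::create(_["W"] = W, _["H"] = H,
                      _["error"] = NumericVector(err.begin(), err.end()),
                      _["iterations"] = it);
}
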