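#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF under Frobenius loss (Lee & Seung updates).
// V (m x n) >= 0 is factorized as W (m x k) * H (k x n), W, H >= 0.
// Initial factors are supplied by the caller so that all randomness is
// controlled by R's RNG. When update_w is false, W is held fixed and only
// H is updated (reference-based recovery). The objective is checked every
// `check_every` iterations; iteration stops when the relative decrease of
// the Frobenius error falls below `tol` or `maxiter` is reached.
// [[Rcpp::export(name = ".nmf_mu")]]
List nmf_mu(const arma::mat& V, arma::mat W, arma::mat H,
            const int maxiter, const double tol,
            const bool update_w, const int check_every) {
  const double eps = 1e-12;
  double prev = arma::norm(V - W * H, "fro");
  std::vector<double> trace;
  trace.push_back(prev);
  int iter = 0;
  for (iter = 1; iter <= maxiter; ++iter) {
    // H <- H .* (W'V) ./ (W'W H)
    H %= (W.t() * V) / (W.t() * W * H + eps);
    if (update_w) {
      // W <- W .* (V H') ./ (W H H')
      W %= (V * H.t()) / (W * (H * H.t()) + eps);
    }
    if (iter % check_every == 0 || iter == maxiter) {
      double cur = arma::norm(V - W * H, "fro");
      if (!std::isfinite(cur)) {
        stop("non-finite reconstruction error at iteration %d", iter);
      }
      trace.push_back(cur);
      if (prev > 0 && (prev - cur) / prev < tol) {
        prev = cur;
        break;
      }
      prev = cur;
    }
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["objective"] = wrap(trace),
                      _["iterations"] = std::min(iter, maxiter));
}
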