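// Multiplicative-update non-negative matrix factorization (Frobenius objective).
// The restart loop and initialization live in R so that all randomness goes
// through R's RNG; this routine is deterministic given (V, W0, H0).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, const arma::mat& W0,
                      const arma::mat& H0, int max_iter, double tol,
                      int window, bool keep_trace) {
  const double eps = 1e-12;
  mat W = W0, H = H0;
  std::vector<double> trace;
  if (keep_trace) trace.reserve(max_iter + 1);

  double sse = accu(square(V - W * H));
  double sse_prev_window = sse;
  if (keep_trace) trace.push_back(sse);

  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // H <- H .* (W'V) ./ (W'WH)
    H %= (W.t() * V) / ((W.t() * W) * H + eps);
    // W <- W .* (VH') ./ (WHH')
    W %= (V * H.t()) / (W * (H * H.t()) + eps);

    // the convergence rule compares SSE across a `window`-iteration span;
    // off the tracing path the objective is only evaluated at those checks
    if (keep_trace) {
      sse = accu(square(V - W * H));
      trace.push_back(sse);
      if (iter >= window) {
        double prev = trace[iter - window];
        if (prev <= 0.0 || (prev - sse) / prev < tol) break;
      }
    } else if (iter % window == 0) {
      sse = accu(square(V - W * H));
      if (sse_prev_window <= 0.0 ||
          (sse_prev_window - sse) / sse_prev_window < tol) break;
      sse_prev_window = sse;
    }
  }
  sse = accu(square(V - W * H));

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H, Rcpp::Named("sse") = sse,
      Rcpp::Named("iterations") = std::min(iter, max_iter));
  if (keep_trace)
    out["sse_trace"] = Rcpp::NumericVector(trace.begin(), trace.end());
  return out;
}
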