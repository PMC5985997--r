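#include <Rcpp.h>

using namespace Rcpp;

// Normalized fluctuation autocorrelation at integer bin lags:
//   G_k = mean over valid t of (F(t) - mu)(F(t+k) - mu) / mu^2
// with mu the global trace mean. Non-circular (truncated) products by
// default; the circular convention exists for periodic test fixtures.
// [[Rcpp::export(name = ".corr_at_lags_cpp")]]
List corr_at_lags_cpp(NumericVector x, IntegerVector lags, bool circular) {
  const R_xlen_t n = x.size();
  double mu = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) mu += x[i];
  mu /= (double)n;
  if (mu == 0.0) stop("trace mean is zero: autocorrelation undefined");
  const double mu2 = mu * mu;

  const int nl = lags.size();
  NumericVector g(nl);
  NumericVector nprod(nl);
  for (int j = 0; j < nl; ++j) {
    const R_xlen_t k = lags[j];
    if (k < 0 || k >= n) stop("lag out of range");
    double acc = 0.0;
    if (circular) {
      for (R_xlen_t t = 0; t < n; ++t) {
        R_xlen_t u = t + k;
        if (u >= n) u -= n;
        acc += (x[t] - mu) * (x[u] - mu);
      }
      g[j] = acc / ((double)n * mu2);
      nprod[j] = (double)n;
    } else {
      const R_xlen_t m = n - k;
      for (R_xlen_t t = 0; t < m; ++t)
        acc += (x[t] - mu) * (x[t + k] - mu);
      g[j] = acc / ((double)m * mu2);
      nprod[j] = (double)m;
    }
  }
  return List::create(_["g"] = g, _["n"] = nprod);
}

// Pairwise rebinning: sums of consecutive pairs (odd trailing bin dropped).
// [[Rcpp::export(name = ".rebin2_cpp")]]
NumericVector rebin2_cpp(NumericVector x) {
  const R_xlen_t m = x.size() / 2;
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) out[i] = x[2 * i] + x[2 * i + 1];
  return out;
}
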