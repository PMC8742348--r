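#include <Rcpp.h>
using namespace Rcpp;

// Symmetric-normalized autocorrelation estimator at a set of integer lags:
//   G(k) = sum_{i=1}^{n-k} x_i x_{i+k} / ((n-k) m1(k) m2(k)) - 1
// with m1, m2 the means of the lag-matched leading/trailing segments.
// This is the standard finite-trace bias correction; every lag is computed
// at full bin resolution.
//
// [[Rcpp::export]]
NumericVector autocorr_lags_cpp(NumericVector x, IntegerVector lags) {
  const int n = x.size();
  const int nl = lags.size();
  NumericVector g(nl);

  // suffix sums for lag-matched means
  std::vector<double> csum(n + 1, 0.0);
  for (int i = 0; i < n; ++i) csum[i + 1] = csum[i] + x[i];

  for (int j = 0; j < nl; ++j) {
    const int k = lags[j];
    if (k <= 0 || k >= n) { g[j] = NA_REAL; continue; }
    const int m = n - k;
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += x[i] * x[i + k];
    const double m1 = csum[m] / m;                 // mean of x[0..m-1]
    const double m2 = (csum[n] - csum[k]) / m;     // mean of x[k..n-1]
    g[j] = (m1 > 0.0 && m2 > 0.0) ? s / (m * m1 * m2) - 1.0 : NA_REAL;
  }
  return g;
}
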