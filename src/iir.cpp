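#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b, a: numerator/denominator coefficients (a[0] need not be 1);
// zi: initial conditions of length max(len(a), len(b)) - 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("leading denominator coefficient must be nonzero");
  for (int i = 0; i < n; ++i) { bb[i] /= a0; aa[i] /= a0; }

  std::vector<double> z(n > 1 ? n - 1 : 1, 0.0);
  for (int i = 0; i < zi.size() && i < n - 1; ++i) z[i] = zi[i];

  int T = x.size();
  NumericVector y(T);
  if (n == 1) {
    for (int t = 0; t < T; ++t) y[t] = bb[0] * x[t];
    return y;
  }
  for (int t = 0; t < T; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < n - 2; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    z[n - 2] = bb[n - 1] * xt - aa[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}
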