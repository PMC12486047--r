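// Envelope extraction for the burst detector.
#include <Rcpp.h>

// Centred moving RMS with edge truncation (partial windows at the edges
// use the samples present).
// [[Rcpp::export]]
Rcpp::NumericVector moving_rms_cpp(const Rcpp::NumericVector& x,
                                   const int w) {
  const int n = x.size();
  Rcpp::NumericVector out(n);
  if (w <= 1) {
    for (int i = 0; i < n; ++i) out[i] = std::fabs(x[i]);
    return out;
  }
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i] * x[i];
  const int half = w / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - half; if (lo < 0) lo = 0;
    int hi = i + (w - half - 1); if (hi > n - 1) hi = n - 1;
    out[i] = std::sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1));
  }
  return out;
}
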