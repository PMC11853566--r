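#include <Rcpp.h>
using namespace Rcpp;

// Template match counts for sample entropy.
// Both template sets use starting points 1..n-m so every m-length template
// has a corresponding (m+1)-length extension; self-matches excluded.
// B = pairs of m-length templates within Chebyshev distance r,
// A = pairs also matching at the (m+1)-th point.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  double A = 0.0, B = 0.0;
  int nm = n - m;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
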