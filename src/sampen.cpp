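#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy.
// B = number of pairs (i < j), i, j in 0..(n-m-1), whose length-m templates
// are within Chebyshev distance r; A = same index range at length m+1.
// Self-matches are excluded by construction (i < j).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // templates of length m and m+1 both indexed 0..nt-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dm = std::fabs(x[i + m] - x[j + m]);
      if (dm > d) d = dm;
      if (d <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
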