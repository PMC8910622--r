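#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
// Templates of length m start at i = 0..N-m-1 (0-based), so that every
// m-template counted also has an (m+1)-extension; pairs i < j are counted
// once (the symmetric double count cancels in the ratio A/B).
// Returns c(A, B): A = matches at length m+1, B = matches at length m,
// Chebyshev distance, tolerance comparison <= r, self-matches excluded.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of (m+1)-capable template starts
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm <= d) dm = d;
        if (dm <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Averaged Higuchi curve lengths H(k) for k = 1..kmax.
// For each lag k and offset m = 1..k (1-based), the normalized curve length
// is  (N-1) / (floor((N-m)/k) * k^2) * sum_{i=1}^{floor((N-m)/k)}
//     |X(m + i k) - X(m + (i-1) k)| ,
// and H(k) is the mean over the k offsets.
// [[Rcpp::export]]
NumericVector higuchi_lengths(NumericVector x, int kmax) {
  const int n = x.size();
  NumericVector H(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double acc = 0.0;
    for (int m = 1; m <= k; ++m) {
      int cnt = (n - m) / k;
      if (cnt < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= cnt; ++i) {
        s += std::fabs(x[m + i * k - 1] - x[m + (i - 1) * k - 1]);
      }
      acc += s * (double)(n - 1) / ((double)cnt * (double)k * (double)k);
    }
    H[k - 1] = acc / (double)k;
  }
  return H;
}
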