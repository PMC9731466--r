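#include <Rcpp.h>
using namespace Rcpp;

// Pairwise normalized Hamming distance between rows of an integer-coded
// sequence matrix.  0 encodes padding; positions where either row is padded
// are excluded from the comparison.  Rows with no overlap get distance 1.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dist(const IntegerMatrix& m) {
  const int n = m.nrow(), L = m.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int mm = 0, ov = 0;
      for (int k = 0; k < L; ++k) {
        const int a = m(i, k), b = m(j, k);
        if (a && b) {
          ++ov;
          if (a != b) ++mm;
        }
      }
      const double v = ov ? (double)mm / ov : 1.0;
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}

// Normalized Hamming distance of one integer-coded row against each row of m.
// [[Rcpp::export]]
NumericVector cpp_row_dist(const IntegerMatrix& m, const IntegerVector& v) {
  const int n = m.nrow();
  const int L = std::min((int)m.ncol(), (int)v.size());
  NumericVector d(n);
  for (int i = 0; i < n; ++i) {
    int mm = 0, ov = 0;
    for (int k = 0; k < L; ++k) {
      const int a = m(i, k), b = v[k];
      if (a && b) {
        ++ov;
        if (a != b) ++mm;
      }
    }
    d[i] = ov ? (double)mm / ov : 1.0;
  }
  return d;
}

// Raw mismatch count between two equal-length integer vectors (no padding).
// [[Rcpp::export]]
int cpp_hamming(const IntegerVector& a, const IntegerVector& b) {
  const int L = std::min(a.size(), b.size());
  int mm = 0;
  for (int k = 0; k < L; ++k)
    if (a[k] != b[k]) ++mm;
  return mm;
}
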