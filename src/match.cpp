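#include <Rcpp.h>
using namespace Rcpp;

// Argmax inner product of each row of X (n x k) against rows of A (m x k).
// Both are expected row-normalised by the caller. Ties resolve to the first
// (lowest) atom index, matching the documented tie-break ordering.
// Returns 1-based indices and the winning inner products without
// materialising the n x m score matrix.
// [[Rcpp::export]]
List cpp_argmax_inner(NumericMatrix X, NumericMatrix A) {
  const int n = X.nrow(), k = X.ncol(), m = A.nrow();
  if (A.ncol() != k) stop("dimension mismatch");
  // pack A transposed and contiguous: At[j*k + c]
  std::vector<double> At((size_t)m * k);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < k; ++c) At[(size_t)j * k + c] = A(j, c);
  IntegerVector idx(n);
  NumericVector best(n);
  std::vector<double> x(k);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < k; ++c) x[c] = X(i, c);
    double b = -2.0; int bj = 0;
    const double* a = At.data();
    if (k == 4) {  // hot path: 4-point signal evolutions
      for (int j = 0; j < m; ++j, a += 4) {
        double s = x[0] * a[0] + x[1] * a[1] + x[2] * a[2] + x[3] * a[3];
        if (s > b) { b = s; bj = j; }
      }
    } else {
      for (int j = 0; j < m; ++j, a += k) {
        double s = 0.0;
        for (int c = 0; c < k; ++c) s += x[c] * a[c];
        if (s > b) { b = s; bj = j; }
      }
    }
    idx[i] = bj + 1;
    best[i] = b;
  }
  return List::create(_["idx"] = idx, _["best"] = best);
}
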