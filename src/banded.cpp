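#include <Rcpp.h>
using namespace Rcpp;

// Solve A x = b for a symmetric positive-definite pentadiagonal matrix A
// given by its main diagonal d0 (length n), first sub/super-diagonal d1
// (length n-1) and second sub/super-diagonal d2 (length n-2), via a banded
// Cholesky factorization A = L L^T with bandwidth 2. O(n) time and memory.
//
// This is the inner solve of the asymmetric least squares baseline
// iteration, where A = W + lambda * D2' D2 (W diagonal weights, D2 the
// second-difference operator on an index grid).
// [[Rcpp::export]]
NumericVector penta_chol_solve(NumericVector d0, NumericVector d1,
                               NumericVector d2, NumericVector b) {
  const int n = d0.size();
  if (d1.size() != n - 1 || d2.size() != n - 2 || b.size() != n)
    stop("inconsistent band/rhs lengths");
  if (n < 3) stop("system too small for a pentadiagonal solve");

  // L stored as: l0 = diag, l1 = first subdiagonal, l2 = second subdiagonal
  std::vector<double> l0(n), l1(n - 1), l2(n - 2);

  for (int i = 0; i < n; ++i) {
    double s = d0[i];
    if (i >= 1) s -= l1[i - 1] * l1[i - 1];
    if (i >= 2) s -= l2[i - 2] * l2[i - 2];
    if (s <= 0.0) stop("matrix not positive definite");
    l0[i] = std::sqrt(s);

    if (i + 1 < n) {
      double t = d1[i];
      if (i >= 1) t -= l1[i - 1] * l2[i - 1];
      l1[i] = t / l0[i];
    }
    if (i + 2 < n) l2[i] = d2[i] / l0[i];
  }

  // forward substitution L y = b
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    if (i >= 1) s -= l1[i - 1] * y[i - 1];
    if (i >= 2) s -= l2[i - 2] * y[i - 2];
    y[i] = s / l0[i];
  }

  // back substitution L^T x = y
  NumericVector x(n);
  for (int i = n - 1; i >= 0; --i) {
    double s = y[i];
    if (i + 1 < n) s -= l1[i] * x[i + 1];
    if (i + 2 < n) s -= l2[i] * x[i + 2];
    x[i] = s / l0[i];
  }
  return x;
}
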