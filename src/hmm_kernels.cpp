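// Inner-loop kernels for the factored-HMM forward/backward pass.
// Factors are sparse column-compressed (dgCMatrix slots passed directly);
// alpha/beta blocks are dense reads x states matrices.

#include <Rcpp.h>
using namespace Rcpp;

// A %*% M for a sparse M given by its CSC slots (i, p, x).
// [[Rcpp::export]]
NumericMatrix dense_sparse_prod(NumericMatrix A, IntegerVector Mi,
                                IntegerVector Mp, NumericVector Mx,
                                int ncol_m) {
  const int n = A.nrow();
  NumericMatrix out(n, ncol_m);
  for (int j = 0; j < ncol_m; ++j) {
    double* outj = &out(0, j);
    for (int idx = Mp[j]; idx < Mp[j + 1]; ++idx) {
      const double v = Mx[idx];
      const double* ai = &A(0, Mi[idx]);
      for (int r = 0; r < n; ++r) outj[r] += v * ai[r];
    }
  }
  return out;
}

// colSums(A * B) without materializing the elementwise product.
// [[Rcpp::export]]
NumericVector colsums_prod(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), s = A.ncol();
  NumericVector out(s);
  for (int j = 0; j < s; ++j) {
    const double* aj = &A(0, j);
    const double* bj = &B(0, j);
    double acc = 0.0;
    for (int r = 0; r < n; ++r) acc += aj[r] * bj[r];
    out[j] = acc;
  }
  return out;
}

// Apply emission densities (D indexed per state through kindex, 1-based) and
// rescale each row to sum one. Returns the scaled matrix plus the row sums
// used for scaling (the per-read likelihood contributions).
// [[Rcpp::export]]
List emission_scale(NumericMatrix A, NumericMatrix D, IntegerVector kindex) {
  const int n = A.nrow(), s = A.ncol();
  NumericMatrix out(n, s);
  NumericVector sc(n);
  for (int j = 0; j < s; ++j) {
    const double* aj = &A(0, j);
    const double* dj = &D(0, kindex[j] - 1);
    double* oj = &out(0, j);
    for (int r = 0; r < n; ++r) {
      const double v = aj[r] * dj[r];
      oj[r] = v;
      sc[r] += v;
    }
  }
  for (int j = 0; j < s; ++j) {
    double* oj = &out(0, j);
    for (int r = 0; r < n; ++r) oj[r] /= sc[r];
  }
  return List::create(_["A"] = out, _["scale"] = sc);
}

// Apply emission densities and divide by precomputed row scales (backward
// pass counterpart of emission_scale).
// [[Rcpp::export]]
NumericMatrix emission_divide(NumericMatrix B, NumericMatrix D,
                              IntegerVector kindex, NumericVector sc) {
  const int n = B.nrow(), s = B.ncol();
  NumericMatrix out(n, s);
  for (int j = 0; j < s; ++j) {
    const double* bj = &B(0, j);
    const double* dj = &D(0, kindex[j] - 1);
    double* oj = &out(0, j);
    for (int r = 0; r < n; ++r) oj[r] = bj[r] * dj[r] / sc[r];
  }
  return out;
}
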