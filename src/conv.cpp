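#include <Rcpp.h>
using namespace Rcpp;

// 1-D convolution patch gather/scatter for the CNN path.
//
// Activations travel in "transposed" layout: one column per sample, rows are
// channel-fastest within position. For an input of C channels and length L,
// X is (C*L) x n. Patches for a filter of width w are the contiguous row
// blocks C*p .. C*p + C*w - 1, so gathering them is a straight copy.

// [[Rcpp::export]]
NumericMatrix im2col_t(const NumericMatrix& X, int C, int L, int w) {
  // Returns (C*w) x (P*n); within each sample, columns are ordered by
  // position p = 1..P with P = L - w + 1.
  const int n = X.ncol(), P = L - w + 1, Cw = C * w;
  if (X.nrow() != C * L) stop("im2col_t: nrow(X) != C*L");
  if (P < 1) stop("im2col_t: filter wider than input");
  NumericMatrix out(Cw, P * n);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + (size_t)i * C * L;
    double* oi = op + (size_t)i * P * Cw;
    for (int p = 0; p < P; ++p)
      std::copy(xi + (size_t)C * p, xi + (size_t)C * p + Cw, oi + (size_t)p * Cw);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_t(const NumericMatrix& dPM, int C, int L, int w, int n) {
  // Adjoint of im2col_t: accumulates overlapping patch gradients back onto
  // the (C*L) x n input gradient.
  const int P = L - w + 1, Cw = C * w;
  if (dPM.nrow() != Cw || dPM.ncol() != P * n) stop("col2im_t: bad dPM shape");
  NumericMatrix dX(C * L, n);
  const double* dp = dPM.begin();
  double* xp = dX.begin();
  for (int i = 0; i < n; ++i) {
    double* xi = xp + (size_t)i * C * L;
    const double* di = dp + (size_t)i * P * Cw;
    for (int p = 0; p < P; ++p) {
      const double* col = di + (size_t)p * Cw;
      double* dst = xi + (size_t)C * p;
      for (int j = 0; j < Cw; ++j) dst[j] += col[j];
    }
  }
  return dX;
}
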