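#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix (im2col) lowering for 2-D convolution on H x W x C arrays
// stored in R's column-major order, in output-position-major orientation:
// the result has one ROW per output position (io + Ho*jo) and one COLUMN
// per kernel tap (ki + kh*(kj + kw*c)), matching matrix(w, kh*kw*C, Cout)
// on the R side, so conv forward is a single GEMM cols %*% wmat with no
// transposes. Writes within a column run down io and are contiguous.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t n = (R_xlen_t)Ho * Wo;
  NumericMatrix cols(n, kh * kw * C);
  const double* px = x.begin();
  double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double* ccol = pc + n * r;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const double* xcol = px + H * (j + (R_xlen_t)W * c);
          double* cpos = ccol + (R_xlen_t)Ho * jo;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            cpos[io] = xcol[i];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add patch-matrix entries back into an
// H x W x C array. Used for conv input-gradients and for the forward pass
// of transposed convolution.

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t n = (R_xlen_t)Ho * Wo;
  NumericVector x((R_xlen_t)H * W * C);
  const double* pc = cols.begin();
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double* ccol = pc + n * r;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* xcol = px + H * (j + (R_xlen_t)W * c);
          const double* cpos = ccol + (R_xlen_t)Ho * jo;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            xcol[i] += cpos[io];
          }
        }
      }
    }
  }
  return x;
}
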