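#include <Rcpp.h>
using namespace Rcpp;

// Feature tensors are stored as C x (H*W*N) matrices, column index
// h + H*(w + W*n).  im2col rows are ordered c + C*(p + kh*q) so that a
// weight matrix of shape (Cout, C*kh*kw) multiplies the column matrix
// directly.  Out-of-range taps read as zero (zero padding).

// [[Rcpp::export]]
NumericMatrix conv_im2col(const NumericMatrix& x, int H, int W, int N,
                          int kh, int kw, int stride, int pad) {
  const int C = x.nrow();
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = C * kh * kw;
  NumericMatrix col(K, Ho * Wo * N);
  const double* px = x.begin();
  double* pc = col.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t cidx = (R_xlen_t)(ho + Ho * (wo + (R_xlen_t)Wo * n)) * K;
        for (int q = 0; q < kw; ++q) {
          const int w = wo * stride - pad + q;
          for (int p = 0; p < kh; ++p) {
            const int h = ho * stride - pad + p;
            if (h < 0 || h >= H || w < 0 || w >= W) continue;
            const R_xlen_t xoff = (R_xlen_t)(h + H * (w + (R_xlen_t)W * n)) * C;
            double* dst = pc + cidx + C * (p + kh * q);
            const double* src = px + xoff;
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericMatrix conv_col2im(const NumericMatrix& col, int C, int H, int W, int N,
                          int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = C * kh * kw;
  NumericMatrix x(C, H * W * N);
  const double* pc = col.begin();
  double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t cidx = (R_xlen_t)(ho + Ho * (wo + (R_xlen_t)Wo * n)) * K;
        for (int q = 0; q < kw; ++q) {
          const int w = wo * stride - pad + q;
          for (int p = 0; p < kh; ++p) {
            const int h = ho * stride - pad + p;
            if (h < 0 || h >= H || w < 0 || w >= W) continue;
            const R_xlen_t xoff = (R_xlen_t)(h + H * (w + (R_xlen_t)W * n)) * C;
            const double* src = pc + cidx + C * (p + kh * q);
            double* dst = px + xoff;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}
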