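#include <Rcpp.h>
using namespace Rcpp;

// Bilinear resize of a C x (H*W*N) tensor to C x (Ho*Wo*N), half-pixel
// centre alignment with edge clamping (matches bilinearMatrix on the R
// side).  Each output pixel mixes at most 4 taps, so the direct loop
// beats a dense matrix product.

static void bilinear_taps(int nIn, int nOut, std::vector<int>& lo,
                          std::vector<int>& hi, std::vector<double>& fr) {
  lo.resize(nOut); hi.resize(nOut); fr.resize(nOut);
  for (int i = 0; i < nOut; ++i) {
    double src = (i + 0.5) * (double)nIn / nOut - 0.5;
    double fl = std::floor(src);
    double f = src - fl;
    int l = (int)fl;
    int l0 = std::min(std::max(l, 0), nIn - 1);
    int h0 = std::min(l + 1, nIn - 1);
    lo[i] = l0; hi[i] = h0; fr[i] = f;
  }
}

// [[Rcpp::export]]
NumericMatrix resize_bilinear(const NumericMatrix& x, int H, int W, int N,
                              int Ho, int Wo) {
  const int C = x.nrow();
  std::vector<int> hlo, hhi, wlo, whi;
  std::vector<double> hfr, wfr;
  bilinear_taps(H, Ho, hlo, hhi, hfr);
  bilinear_taps(W, Wo, wlo, whi, wfr);
  NumericMatrix out(C, (R_xlen_t)Ho * Wo * N);
  const double* px = x.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = px + (R_xlen_t)n * H * W * C;
    double* on = po + (R_xlen_t)n * Ho * Wo * C;
    for (int j = 0; j < Wo; ++j) {
      const double fw = wfr[j];
      const double* cLo = xn + (R_xlen_t)wlo[j] * H * C;
      const double* cHi = xn + (R_xlen_t)whi[j] * H * C;
      for (int i = 0; i < Ho; ++i) {
        const double fh = hfr[i];
        const double w00 = (1 - fh) * (1 - fw), w10 = fh * (1 - fw);
        const double w01 = (1 - fh) * fw, w11 = fh * fw;
        const double* p00 = cLo + (R_xlen_t)hlo[i] * C;
        const double* p10 = cLo + (R_xlen_t)hhi[i] * C;
        const double* p01 = cHi + (R_xlen_t)hlo[i] * C;
        const double* p11 = cHi + (R_xlen_t)hhi[i] * C;
        double* dst = on + (R_xlen_t)(i + Ho * j) * C;
        for (int c = 0; c < C; ++c)
          dst[c] = w00 * p00[c] + w10 * p10[c] + w01 * p01[c] + w11 * p11[c];
      }
    }
  }
  return out;
}

// Adjoint of resize_bilinear: scatter output-side gradients back through
// the same taps and weights.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_grad(const NumericMatrix& dout, int H, int W,
                                   int N, int Ho, int Wo) {
  const int C = dout.nrow();
  std::vector<int> hlo, hhi, wlo, whi;
  std::vector<double> hfr, wfr;
  bilinear_taps(H, Ho, hlo, hhi, hfr);
  bilinear_taps(W, Wo, wlo, whi, wfr);
  NumericMatrix dx(C, (R_xlen_t)H * W * N);
  const double* pd = dout.begin();
  double* px = dx.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = px + (R_xlen_t)n * H * W * C;
    const double* on = pd + (R_xlen_t)n * Ho * Wo * C;
    for (int j = 0; j < Wo; ++j) {
      const double fw = wfr[j];
      double* cLo = xn + (R_xlen_t)wlo[j] * H * C;
      double* cHi = xn + (R_xlen_t)whi[j] * H * C;
      for (int i = 0; i < Ho; ++i) {
        const double fh = hfr[i];
        const double w00 = (1 - fh) * (1 - fw), w10 = fh * (1 - fw);
        const double w01 = (1 - fh) * fw, w11 = fh * fw;
        double* p00 = cLo + (R_xlen_t)hlo[i] * C;
        double* p10 = cLo + (R_xlen_t)hhi[i] * C;
        double* p01 = cHi + (R_xlen_t)hlo[i] * C;
        double* p11 = cHi + (R_xlen_t)hhi[i] * C;
        const double* src = on + (R_xlen_t)(i + Ho * j) * C;
        for (int c = 0; c < C; ++c) {
          p00[c] += w00 * src[c];
          p10[c] += w10 * src[c];
          p01[c] += w01 * src[c];
          p11[c] += w11 * src[c];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix relu_fwd(const NumericMatrix& x) {
  NumericMatrix out = clone(x);
  double* p = out.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix relu_bwd(const NumericMatrix& dout, const NumericMatrix& out) {
  NumericMatrix dx = clone(dout);
  double* p = dx.begin();
  const double* o = out.begin();
  const R_xlen_t n = dx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (o[i] <= 0) p[i] = 0;
  return dx;
}

// Mean softmax cross-entropy over the non-ignored columns of a K x P
// logit matrix, with the gradient wrt the logits.  labels are 0-based;
// columns whose label equals `ignore` contribute nothing.
// [[Rcpp::export]]
List softmax_ce_grad(const NumericMatrix& logits, const IntegerVector& labels,
                     int ignore) {
  const int K = logits.nrow();
  const R_xlen_t P = logits.ncol();
  NumericMatrix grad(K, P);
  const double* pl = logits.begin();
  double* pg = grad.begin();
  double loss = 0.0;
  R_xlen_t nValid = 0;
  std::vector<double> e(K);
  for (R_xlen_t j = 0; j < P; ++j) {
    const int lab = labels[j];
    if (lab == ignore) continue;
    const double* col = pl + j * K;
    double m = col[0];
    for (int k = 1; k < K; ++k) if (col[k] > m) m = col[k];
    double s = 0.0;
    for (int k = 0; k < K; ++k) { e[k] = std::exp(col[k] - m); s += e[k]; }
    double* g = pg + j * K;
    for (int k = 0; k < K; ++k) g[k] = e[k] / s;
    loss += std::log(s) + m - col[lab];
    g[lab] -= 1.0;
    ++nValid;
  }
  if (nValid == 0) stop("all entries are ignored");
  const double inv = 1.0 / (double)nValid;
  const R_xlen_t tot = grad.size();
  for (R_xlen_t i = 0; i < tot; ++i) pg[i] *= inv;
  return List::create(_["loss"] = loss * inv, _["grad"] = grad);
}
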