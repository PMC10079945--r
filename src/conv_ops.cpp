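// Compiled kernels for the network's data-movement hot paths: im2col patch
// extraction (with implicit zero padding), its col2im adjoint, and 2D max
// pooling with argmax bookkeeping. Feature maps are laid out channels-first
// as (C, H, W, B) column-major arrays so convolution outputs reshape into
// place without transposition.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Patch matrix: rows ordered (kh, kw, c), columns (ho, wo, b); stride 1.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& A, int C, int H, int W, int B,
                         int K, int P) {
  const int Ho = H + 2 * P - K + 1, Wo = W + 2 * P - K + 1;
  const int nr = K * K * C;
  const R_xlen_t nc = (R_xlen_t)Ho * Wo * B;
  NumericMatrix out(nr, nc);
  const double* pa = A.begin();
  double* po = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* ab = pa + (R_xlen_t)b * C * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = po + ((R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * b)) * nr;
        for (int c = 0; c < C; ++c)
          for (int kw = 0; kw < K; ++kw) {
            const int w = wo + kw - P;
            double* d2 = dst + K * kw + K * K * c;
            if (w < 0 || w >= W) {
              for (int kh = 0; kh < K; ++kh) d2[kh] = 0.0;
              continue;
            }
            const double* col = ab + c + (R_xlen_t)C * H * w;
            for (int kh = 0; kh < K; ++kh) {
              const int h = ho + kh - P;
              d2[kh] = (h < 0 || h >= H) ? 0.0 : col[(R_xlen_t)C * h];
            }
          }
      }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients onto the input.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dPm, int C, int H, int W,
                         int B, int K, int P) {
  const int Ho = H + 2 * P - K + 1, Wo = W + 2 * P - K + 1;
  const int nr = dPm.nrow();
  NumericVector dA((R_xlen_t)C * H * W * B);
  const double* pm = dPm.begin();
  double* pa = dA.begin();
  for (int b = 0; b < B; ++b) {
    double* ab = pa + (R_xlen_t)b * C * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double* src =
          pm + ((R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * b)) * nr;
        for (int c = 0; c < C; ++c)
          for (int kw = 0; kw < K; ++kw) {
            const int w = wo + kw - P;
            if (w < 0 || w >= W) continue;
            const double* s2 = src + K * kw + K * K * c;
            double* col = ab + c + (R_xlen_t)C * H * w;
            for (int kh = 0; kh < K; ++kh) {
              const int h = ho + kh - P;
              if (h >= 0 && h < H) col[(R_xlen_t)C * h] += s2[kh];
            }
          }
      }
  }
  dA.attr("dim") = IntegerVector::create(C, H, W, B);
  return dA;
}

// Max pooling on (C, H, W, B); ties keep the first (smallest-offset) pixel.
// `arg` records, per output element, the 0-based linear index of the winning
// input element, for the backward routing.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& A, int C, int H, int W, int B,
                     int K, int S) {
  const int Ho = (H - K) / S + 1, Wo = (W - K) / S + 1;
  NumericVector out((R_xlen_t)C * Ho * Wo * B);
  IntegerVector arg(out.size());
  const double* pa = A.begin();
  double* po = out.begin();
  int* pg = arg.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t base = (R_xlen_t)b * C * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c, ++o) {
          double best = -DBL_MAX;
          R_xlen_t bi = 0;
          for (int kw = 0; kw < K; ++kw)
            for (int kh = 0; kh < K; ++kh) {
              const R_xlen_t idx = base + c +
                (R_xlen_t)C * (ho * S + kh) + (R_xlen_t)C * H * (wo * S + kw);
              if (pa[idx] > best) { best = pa[idx]; bi = idx; }
            }
          po[o] = best;
          pg[o] = (int)bi;
        }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dOut,
                              const IntegerVector& arg,
                              int C, int H, int W, int B) {
  NumericVector dA((R_xlen_t)C * H * W * B);
  double* pa = dA.begin();
  const double* po = dOut.begin();
  const int* pg = arg.begin();
  const R_xlen_t n = dOut.size();
  for (R_xlen_t i = 0; i < n; ++i) pa[pg[i]] += po[i];
  dA.attr("dim") = IntegerVector::create(C, H, W, B);
  return dA;
}
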