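// Patch extraction (im2col) and its adjoint scatter-add (col2im) for the
// convolution engine. Tensors are column-major (H, W, B, C) arrays; the
// patch matrix has rows ordered (ho, wo, b) and columns ordered
// (dh, dw, c), matching a column-major flatten of a (kh, kw, C, Cout)
// kernel. Matrix products stay in R (BLAS).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int B, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t n = (R_xlen_t)Ho * Wo * B;
  NumericMatrix P(n, (R_xlen_t)kh * kw * C);
  const double* xp = x.begin();
  double* pp = P.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const R_xlen_t col = (R_xlen_t)c * kh * kw + dw * kh + dh;
        double* dst = pp + col * n;
        for (int b = 0; b < B; ++b) {
          const double* xs = xp + ((R_xlen_t)c * B + b) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dw - pad;
            double* d2 = dst + (R_xlen_t)b * Ho * Wo + (R_xlen_t)wo * Ho;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) d2[ho] = 0.0;
              continue;
            }
            const double* xc = xs + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + dh - pad;
              d2[ho] = (hi >= 0 && hi < H) ? xc[hi] : 0.0;
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, int H, int W, int B, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t n = (R_xlen_t)Ho * Wo * B;
  NumericVector dx((R_xlen_t)H * W * B * C);  // zero-initialized
  double* xp = dx.begin();
  const double* pp = dP.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const R_xlen_t col = (R_xlen_t)c * kh * kw + dw * kh + dh;
        const double* src = pp + col * n;
        for (int b = 0; b < B; ++b) {
          double* xs = xp + ((R_xlen_t)c * B + b) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dw - pad;
            if (wi < 0 || wi >= W) continue;
            const double* s2 = src + (R_xlen_t)b * Ho * Wo +
              (R_xlen_t)wo * Ho;
            double* xc = xs + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + dh - pad;
              if (hi >= 0 && hi < H) xc[hi] += s2[ho];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}
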