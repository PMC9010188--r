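// Patch-matrix (im2col/col2im) and max-pooling primitives for the residual
// CNN. Convolutions themselves are BLAS matrix products on the R side;
// these kernels only rearrange memory, which is the part R is slow at.
// Arrays are column-major H x W x C, matching R's array layout.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(Ho * Wo, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        double *dst = &out(0, col);
        const double *src = &x[H * W * c];
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            dst[ho + Ho * wo] = src[hi + H * wi];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        const double *src = &cols(0, col);
        double *dst = &x[H * W * c];
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            dst[hi + H * wi] += src[ho + Ho * wo];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling; padded cells act as -Inf. Returns pooled values and the
// 1-based argmax index into the input for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C,
                     int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out(Ho * Wo * C);
  IntegerVector arg(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double *src = &x[H * W * c];
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int j = 0; j < k; ++j) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            const double v = src[hi + H * wi];
            if (v > best) { best = v; besti = hi + H * wi; }
          }
        }
        const int o = ho + Ho * (wo + Wo * c);
        out[o] = best;
        arg[o] = H * W * c + besti + 1;  // 1-based into full array
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["dim"] = IntegerVector::create(Ho, Wo, C));
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              int n_in) {
  NumericVector dx(n_in);
  for (int i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  return dx;
}
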