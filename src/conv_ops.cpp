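// Low-level kernels for the built-in CNN engine.
// Tensors are R arrays with dim (H, W, C, N), column-major, double.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Unfold x into a (kh*kw*C) x (Ho*Wo*N) matrix. Row order: kernel row
// fastest, then kernel col, then channel; column order: output row fastest,
// then output col, then sample. Zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericMatrix out(kh * kw * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int nrow = kh * kw * C;

  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)ho + (long)Ho * (wo + (long)Wo * n);
        double* oc = op + col * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + (long)H * W * (c + (long)C * n);
          for (int j = 0; j < kw; ++j) {
            const int w = w0 + j;
            for (int i = 0; i < kh; ++i) {
              const int h = h0 + i;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + (long)H * w];
              oc[i + kh * (j + kw * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add the column matrix back to input-shaped gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* xp = dx.begin();
  const double* cp = cols.begin();
  const int nrow = kh * kw * C;

  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)ho + (long)Ho * (wo + (long)Wo * n);
        const double* cc = cp + col * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* xc = xp + (long)H * W * (c + (long)C * n);
          for (int j = 0; j < kw; ++j) {
            const int w = w0 + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int h = h0 + i;
              if (h < 0 || h >= H) continue;
              xc[h + (long)H * w] += cc[i + kh * (j + kw * c)];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling, no padding. Returns pooled values and 1-based flat argmax
// indices into x (for the backward scatter).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector arg((long)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ap = arg.begin();


  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long base = (long)H * W * (c + (long)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride, w0 = wo * stride;
          double best = R_NegInf;
          long bi = -1;
          for (int j = 0; j < k; ++j) {
            for (int i = 0; i < k; ++i) {
              const long idx = base + (h0 + i) + (long)H * (w0 + j);
              if (xp[idx] > best) { best = xp[idx]; bi = idx; }
            }
          }
          // y is (Ho,Wo,C,N) but we iterate n,c,wo,ho: compute target index
          const long yi = (long)ho + (long)Ho * (wo + (long)Wo * (c + (long)C * n));
          yp[yi] = best;
          ap[yi] = (double)(bi + 1);

        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, NumericVector argmax,
                              int H, int W, int C, int N) {
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* xp = dx.begin();
  const double* dp = dy.begin();
  const double* ap = argmax.begin();
  const long M = dy.size();
  for (long i = 0; i < M; ++i) xp[(long)ap[i] - 1] += dp[i];
  return dx;
}
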