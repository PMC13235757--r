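#include <Rcpp.h>
using namespace Rcpp;

// Batches of feature maps are numeric arrays with dim (H, W, C, N),
// column-major as R stores them. im2col unrolls k x k patches (stride s,
// zero padding p) into a (k*k*C) x (Hout*Wout*N) matrix so that a
// convolution is a single GEMM against a (Cout x k*k*C) weight matrix.

// [[Rcpp::export]]
NumericMatrix nl_im2col(NumericVector x, int H, int W, int C, int N,
                        int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericMatrix out(k * k * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int patch = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)ho + (long)Ho * (wo + (long)Wo * n);
        double* dst = op + col * patch;
        for (int c = 0; c < C; ++c) {
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * s - p + dw;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * s - p + dh;
              const int r = dh + k * (dw + k * c);
              if (h >= 0 && h < H && w >= 0 && w < W) {
                dst[r] = xp[h + (long)H * (w + (long)W * (c + (long)C * n))];
              } else {
                dst[r] = 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add adjoint of nl_im2col: folds patch-gradient columns back onto
// the (H, W, C, N) input gradient.
// [[Rcpp::export]]
NumericVector nl_col2im(NumericMatrix cols, int H, int W, int C, int N,
                        int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector out((long)H * W * C * N);
  double* op = out.begin();
  const double* cp = cols.begin();
  const int patch = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)ho + (long)Ho * (wo + (long)Wo * n);
        const double* src = cp + col * patch;
        for (int c = 0; c < C; ++c) {
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * s - p + dw;
            if (w < 0 || w >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * s - p + dh;
              if (h < 0 || h >= H) continue;
              const int r = dh + k * (dw + k * c);
              op[h + (long)H * (w + (long)W * (c + (long)C * n))] += src[r];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Max pooling over k x k windows (stride s, zero padding p). Returns the
// pooled maps plus 1-based argmax positions into the flattened input so the
// backward pass is a plain scatter.
// [[Rcpp::export]]
List nl_maxpool(NumericVector x, int H, int W, int C, int N,
                int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector y((long)Ho * Wo * C * N);
  IntegerVector arg((long)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          long bi = -1;
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * s - p + dw;
            if (w < 0 || w >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * s - p + dh;
              if (h < 0 || h >= H) continue;
              const long idx = h + (long)H * (w + (long)W * (c + (long)C * n));
              if (xp[idx] > best) { best = xp[idx]; bi = idx; }
            }
          }
          const long o = (long)ho + (long)Ho * (wo + (long)Wo * (c + (long)C * n));
          yp[o] = (bi >= 0) ? best : 0.0;
          ap[o] = (int)(bi + 1);  // 1-based; 0 marks an all-padding window
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector nl_maxpool_backward(NumericVector dy, IntegerVector argmax,
                                  int H, int W, int C, int N) {
  NumericVector dx((long)H * W * C * N);
  double* dp = dx.begin();
  const double* gp = dy.begin();
  const int* ap = argmax.begin();
  const long M = dy.size();
  for (long i = 0; i < M; ++i) {
    if (ap[i] > 0) dp[ap[i] - 1] += gp[i];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export]]
NumericVector nl_relu(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const long n = y.size();
  for (long i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector nl_relu_backward(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  double* p = dx.begin();
  const double* a = y.begin();
  const long n = dx.size();
  for (long i = 0; i < n; ++i) if (a[i] <= 0) p[i] = 0;
  return dx;
}
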