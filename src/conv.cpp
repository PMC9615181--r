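// Hot inner loops of the convolution engine: im2col / col2im with implicit
// zero padding, and the leaky-rectifier forward/backward. Arrays are
// column-major with dim (H, W, N, C); the im2col column order (kernel row,
// kernel col, channel) matches the R-side flattening of the weight tensor
// (k, k, Cin, Cout).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, const IntegerVector& dims,
                         int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo * N, k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const long col = (long)(a + b * k + c * k * k);
        double* o = op + col * (long)(Ho * Wo * N);
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + ((long)c * N + n) * (long)(H * W);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + b - pad;
            double* orow = o + (long)(n * Wo + wo) * Ho;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) orow[ho] = 0.0;
              continue;
            }
            const double* xcol = xc + (long)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + a - pad;
              orow[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dcol, const IntegerVector& dims,
                         int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((long)H * W * N * C);
  dx.attr("dim") = dims;
  double* dxp = dx.begin();
  const double* dp = dcol.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const long col = (long)(a + b * k + c * k * k);
        const double* d = dp + col * (long)(Ho * Wo * N);
        for (int n = 0; n < N; ++n) {
          double* xc = dxp + ((long)c * N + n) * (long)(H * W);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + b - pad;
            if (wi < 0 || wi >= W) continue;
            const double* drow = d + (long)(n * Wo + wo) * Ho;
            double* xcol = xc + (long)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + a - pad;
              if (hi >= 0 && hi < H) xcol[hi] += drow[ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu(const NumericVector& x, double alpha) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = x[i] > 0 ? x[i] : alpha * x[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_grad(const NumericVector& dy, const NumericVector& x,
                             double alpha) {
  NumericVector out(x.size());
  out.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = x[i] > 0 ? dy[i] : alpha * dy[i];
  }
  return out;
}

// per-channel affine normalization y = (x - mu) * ivstd * gamma + beta over a
// (M x C) matrix view; returns y with xhat as an attribute-free second copy
// [[Rcpp::export]]
List cpp_bn_apply(const NumericVector& x, int C, const NumericVector& mu,
                  const NumericVector& ivstd, const NumericVector& gamma,
                  const NumericVector& beta) {
  const R_xlen_t total = x.size();
  const R_xlen_t M = total / C;
  NumericVector xhat(total), y(total);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], iv = ivstd[c], g = gamma[c], b = beta[c];
    const double* xp = x.begin() + (R_xlen_t)c * M;
    double* hp = xhat.begin() + (R_xlen_t)c * M;
    double* yp = y.begin() + (R_xlen_t)c * M;
    for (R_xlen_t i = 0; i < M; ++i) {
      const double h = (xp[i] - m) * iv;
      hp[i] = h;
      yp[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// direct non-overlapping (kernel == stride) transposed convolution:
// scatter of the per-position GEMM result into the upsampled grid
// ymat: (H*W*N) x (k*k*Cout), column (a + k*b + k*k*co)
// [[Rcpp::export]]
NumericVector cpp_tconv_scatter(const NumericMatrix& ymat,
                                const IntegerVector& dims, int k, int cout) {
  const int H = dims[0], W = dims[1], N = dims[2];
  const int Ho = H * k, Wo = W * k;
  NumericVector y((long)Ho * Wo * N * cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, cout);
  double* yp = y.begin();
  const double* mp = ymat.begin();
  const long Min = (long)H * W * N;
  for (int co = 0; co < cout; ++co) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const double* col = mp + ((long)(a + k * b + k * k * co)) * Min;
        for (int n = 0; n < N; ++n) {
          for (int iw = 0; iw < W; ++iw) {
            const double* src = col + (long)(n * W + iw) * H;
            double* dst = yp + (((long)co * N + n) * Wo + (k * iw + b)) * (long)Ho + a;
            for (int ih = 0; ih < H; ++ih) dst[(long)k * ih] = src[ih];
          }
        }
      }
    }
  }
  return y;
}

// adjoint of cpp_tconv_scatter: gather dy back into (H*W*N) x (k*k*Cout)
// [[Rcpp::export]]
NumericMatrix cpp_tconv_gather(const NumericVector& dy,
                               const IntegerVector& odims, int k) {
  const int Ho = odims[0], Wo = odims[1], N = odims[2], cout = odims[3];
  const int H = Ho / k, W = Wo / k;
  const long Min = (long)H * W * N;
  NumericMatrix out(Min, k * k * cout);
  const double* yp = dy.begin();
  double* mp = out.begin();
  for (int co = 0; co < cout; ++co) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        double* col = mp + ((long)(a + k * b + k * k * co)) * Min;
        for (int n = 0; n < N; ++n) {
          for (int iw = 0; iw < W; ++iw) {
            double* dst = col + (long)(n * W + iw) * H;
            const double* src = yp + (((long)co * N + n) * Wo + (k * iw + b)) * (long)Ho + a;
            for (int ih = 0; ih < H; ++ih) dst[ih] = src[(long)k * ih];
          }
        }
      }
    }
  }
  return out;
}

// fused batch-normalization backward over a (M x C) view
// [[Rcpp::export]]
List cpp_bn_backward(const NumericVector& dy, const NumericVector& xhat,
                     const NumericVector& ivstd, const NumericVector& gamma,
                     int C, bool train) {
  const R_xlen_t total = dy.size();
  const R_xlen_t M = total / C;
  NumericVector dx(total), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dp = dy.begin() + (R_xlen_t)c * M;
    const double* hp = xhat.begin() + (R_xlen_t)c * M;
    double* xp = dx.begin() + (R_xlen_t)c * M;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) {
      s1 += dp[i];
      s2 += dp[i] * hp[i];
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double g = gamma[c], iv = ivstd[c];
    if (train) {
      const double m1 = s1 / M, m2 = s2 / M;
      for (R_xlen_t i = 0; i < M; ++i) {
        xp[i] = g * iv * (dp[i] - m1 - hp[i] * m2);
      }
    } else {
      for (R_xlen_t i = 0; i < M; ++i) xp[i] = g * iv * dp[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// one-pass per-channel mean and (population) variance over a (M x C) view
// [[Rcpp::export]]
List cpp_bn_stats(const NumericVector& x, int C) {
  const R_xlen_t total = x.size();
  const R_xlen_t M = total / C;
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (R_xlen_t)c * M;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) {
      s1 += xp[i];
      s2 += xp[i] * xp[i];
    }
    const double m = s1 / M;
    mu[c] = m;
    va[c] = s2 / M - m * m;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// im2col writing into a caller-owned preallocated buffer (avoids one large
// allocation per convolution call)
// [[Rcpp::export]]
void cpp_im2col_into(NumericMatrix buf, const NumericVector& x,
                     const IntegerVector& dims, int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const double* xp = x.begin();
  double* op = buf.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const long col = (long)(a + b * k + c * k * k);
        double* o = op + col * (long)(Ho * Wo * N);
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + ((long)c * N + n) * (long)(H * W);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + b - pad;
            double* orow = o + (long)(n * Wo + wo) * Ho;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) orow[ho] = 0.0;
              continue;
            }
            const double* xcol = xc + (long)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + a - pad;
              orow[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}
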