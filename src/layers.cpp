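// Compiled kernels for the CNN layers.
//
// Activations are column-major (C, H, W, B) arrays. A 3x3/stride-1/pad-1
// convolution is computed as nine BLAS dgemm calls, one per kernel offset,
// against a shifted view of the zero-padded input assembled with contiguous
// block copies (for a fixed output column and batch item, the C*H elements
// of a shifted slice are contiguous in the padded array).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cstring>

using namespace Rcpp;

// scratch buffers persist across calls: repeated large allocations are
// expensive relative to the kernels themselves
static std::vector<double>& scratch(int which, size_t n) {
  static std::vector<double> buf[2];
  if (buf[which].size() < n) buf[which].resize(n);
  return buf[which];
}

// zero-pad one image (C, H, W) into xp (C, H+2, W+2)
static inline void pad_image(const double* x, double* xp, int C, int H,
                             int W) {
  const int Hp = H + 2, Wp = W + 2;
  std::fill(xp, xp + (size_t)C * Hp * Wp, 0.0);
  for (int w = 0; w < W; ++w)
    std::memcpy(xp + (size_t)C * (1 + Hp * (w + 1)),
                x + (size_t)C * H * w, sizeof(double) * (size_t)C * H);
}

// The convolutions are processed one batch item at a time so that the
// padded image, the shifted views and the output block all stay cache
// resident across the nine kernel-offset GEMMs; each GEMM acts directly on
// a contiguous (C x H) sub-block of the padded image (leading dimension C),
// so no gather copies are needed.

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, IntegerVector xdim,
                              NumericVector w, int cout, NumericVector bias) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], B = xdim[3];
  const int Hp = H + 2;
  NumericVector y((size_t)cout * H * W * B);
  double* yp = REAL(y);
  const double* xpr = REAL(x);
  const double* wp = REAL(w);
  std::vector<double>& xp = scratch(0, (size_t)C * Hp * (W + 2));
  const double one = 1.0;
  for (int b = 0; b < B; ++b) {
    pad_image(xpr + (size_t)C * H * W * b, xp.data(), C, H, W);
    double* yb = yp + (size_t)cout * H * W * b;
    for (int m = 0; m < H * W; ++m)
      for (int o = 0; o < cout; ++o) yb[(size_t)m * cout + o] = bias[o];
    for (int wc = 0; wc < W; ++wc) {
      double* yblock = yb + (size_t)cout * H * wc;
      for (int kx = 0; kx < 3; ++kx)
        for (int ky = 0; ky < 3; ++ky) {
          const double* wk = wp + (size_t)cout * C * (ky + 3 * kx);
          const double* xblock = xp.data() + (size_t)C * (ky + Hp * (wc + kx));
          F77_CALL(dgemm)("N", "N", &cout, &H, &C, &one, wk, &cout,
                          xblock, &C, &one, yblock, &cout FCONE FCONE);
        }
    }
  }
  y.attr("dim") = IntegerVector::create(cout, H, W, B);
  return y;
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector dy, NumericVector x, IntegerVector xdim,
                     NumericVector w, int cout, bool want_dx = true) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], B = xdim[3];
  const int Hp = H + 2;
  const double one = 1.0;
  NumericVector dw((size_t)cout * C * 9);
  NumericVector db(cout);
  NumericVector dx(want_dx ? (size_t)C * H * W * B : 0);
  const double* dyp = REAL(dy);
  const double* xpr = REAL(x);
  const double* wp = REAL(w);
  double* dwp = REAL(dw);
  std::vector<double>& xp = scratch(0, (size_t)C * Hp * (W + 2));
  std::vector<double>& dxp = scratch(1, (size_t)C * Hp * (W + 2));
  for (size_t m = 0, M = (size_t)H * W * B; m < M; ++m)
    for (int o = 0; o < cout; ++o) db[o] += dyp[m * cout + o];
  for (int b = 0; b < B; ++b) {
    pad_image(xpr + (size_t)C * H * W * b, xp.data(), C, H, W);
    if (want_dx)
      std::fill(dxp.begin(), dxp.begin() + (size_t)C * Hp * (W + 2), 0.0);
    const double* dyb = dyp + (size_t)cout * H * W * b;
    for (int wc = 0; wc < W; ++wc) {
      const double* dyblock = dyb + (size_t)cout * H * wc;
      for (int kx = 0; kx < 3; ++kx)
        for (int ky = 0; ky < 3; ++ky) {
          const size_t koff = (size_t)C * (ky + Hp * (wc + kx));
          F77_CALL(dgemm)("N", "T", &cout, &C, &H, &one, dyblock, &cout,
                          xp.data() + koff, &C, &one,
                          dwp + (size_t)cout * C * (ky + 3 * kx),
                          &cout FCONE FCONE);
          if (want_dx)
            F77_CALL(dgemm)("T", "N", &C, &H, &cout, &one,
                            wp + (size_t)cout * C * (ky + 3 * kx), &cout,
                            dyblock, &cout, &one, dxp.data() + koff,
                            &C FCONE FCONE);
        }
    }
    if (want_dx)
      for (int wc = 0; wc < W; ++wc)
        std::memcpy(REAL(dx) + (size_t)C * H * (wc + (size_t)W * b),
                    dxp.data() + (size_t)C * (1 + Hp * (wc + 1)),
                    sizeof(double) * (size_t)C * H);
  }
  dw.attr("dim") = IntegerVector::create(cout, C, 3, 3);
  if (!want_dx)
    return List::create(_["dX"] = R_NilValue, _["dW"] = dw, _["db"] = db);
  dx.attr("dim") = xdim;
  return List::create(_["dX"] = dx, _["dW"] = dw, _["db"] = db);
}

// fused batch-norm + ReLU forward: y = max(0, gamma * xhat + beta)
// [[Rcpp::export]]
NumericVector bn_relu_fwd_cpp(NumericVector x, int C, NumericVector gamma,
                              NumericVector beta, NumericVector mu,
                              NumericVector invstd) {
  const R_xlen_t n = x.size();
  const R_xlen_t M = n / C;
  NumericVector y(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] * invstd[c];
    b[c] = beta[c] - a[c] * mu[c];
  }
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* col = xp + (size_t)m * C;
    double* out = yp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      const double v = a[c] * col[c] + b[c];
      out[c] = v > 0 ? v : 0;
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// fused ReLU + batch-norm backward: the incoming gradient is first masked by
// the ReLU output y, then pushed through the normalization
// [[Rcpp::export]]
List relu_bn_bwd_cpp(NumericVector dy, NumericVector x, NumericVector y,
                     int C, NumericVector gamma, NumericVector mu,
                     NumericVector invstd) {
  const R_xlen_t n = x.size();
  const R_xlen_t M = n / C;
  NumericVector dgamma(C), dbeta(C), dx(n);
  const double* xp = REAL(x);
  const double* yp = REAL(y);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xc = xp + (size_t)m * C;
    const double* yc = yp + (size_t)m * C;
    const double* dc = dyp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      const double g = yc[c] > 0 ? dc[c] : 0;
      const double xhat = (xc[c] - mu[c]) * invstd[c];
      dbeta[c] += g;
      dgamma[c] += g * xhat;
      s1[c] += g;
      s2[c] += g * xhat;
    }
  }
  std::vector<double> m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = gamma[c] * s1[c] / M;
    m2[c] = gamma[c] * s2[c] / M;
  }
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xc = xp + (size_t)m * C;
    const double* yc = yp + (size_t)m * C;
    const double* dc = dyp + (size_t)m * C;
    double* out = dxp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      const double g = yc[c] > 0 ? dc[c] : 0;
      const double xhat = (xc[c] - mu[c]) * invstd[c];
      out[c] = invstd[c] * (gamma[c] * g - m1[c] - xhat * m2[c]);
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dX"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2/stride-2 max pooling; a spatial dimension of size 1 passes through.
// [[Rcpp::export]]
NumericVector maxpool_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], B = xdim[3];
  const int Ho = H >= 2 ? H / 2 : 1, Wo = W >= 2 ? W / 2 : 1;
  const int sh = H >= 2 ? 2 : 1, sw = W >= 2 ? 2 : 1;
  NumericVector y((size_t)C * Ho * Wo * B);
  const double* xpr = REAL(x);
  double* yp = REAL(y);
  for (int b = 0; b < B; ++b)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double* out = yp + (size_t)C * (ho + Ho * (wo + (size_t)Wo * b));
        for (int dw = 0; dw < sw; ++dw)
          for (int dh = 0; dh < sh; ++dh) {
            const double* in = xpr +
              (size_t)C * ((ho * sh + dh) + H * ((wo * sw + dw) + (size_t)W * b));
            if (dh == 0 && dw == 0)
              std::memcpy(out, in, sizeof(double) * C);
            else
              for (int c = 0; c < C; ++c)
                if (in[c] > out[c]) out[c] = in[c];
          }
      }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return y;
}

// gradient routes to the first maximum in (dh, dw) scan order
// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, NumericVector x,
                              IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], B = xdim[3];
  const int Ho = H >= 2 ? H / 2 : 1, Wo = W >= 2 ? W / 2 : 1;
  const int sh = H >= 2 ? 2 : 1, sw = W >= 2 ? 2 : 1;
  NumericVector dx((size_t)C * H * W * B);
  const double* xpr = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int b = 0; b < B; ++b)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t oidx = (size_t)C * (ho + Ho * (wo + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          double best = -1e300;
          size_t best_at = 0;
          for (int dw = 0; dw < sw; ++dw)
            for (int dh = 0; dh < sh; ++dh) {
              const size_t iidx = c +
                (size_t)C * ((ho * sh + dh) + H * ((wo * sw + dw) + (size_t)W * b));
              if (xpr[iidx] > best) { best = xpr[iidx]; best_at = iidx; }
            }
          dxp[best_at] += dyp[oidx + c];
        }
      }
  dx.attr("dim") = xdim;
  return dx;
}

// per-channel mean and biased variance of a (C, M) matrix view
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, int C) {
  const R_xlen_t n = x.size();
  const R_xlen_t M = n / C;
  NumericVector mu(C), var(C);
  const double* xp = REAL(x);
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* col = xp + (size_t)m * C;
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      var[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= M;
    var[c] = var[c] / M - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

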