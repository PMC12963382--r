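// Convolution forward/backward with persistent workspaces and direct BLAS
// calls.  Layout: activations [C, H, W, N] (channel fastest, column-major);
// the GEMM weight matrix is [K x Cout] with K = C*kh*kw, row index
// c + C*(ky + kh*kx).  Workspaces are process-static so repeated training
// iterations allocate nothing.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Convolutions run in single precision internally (inputs/outputs stay
// double): the GEMM shapes here are bandwidth-bound, so float halves the
// traffic, and single precision is the standard numeric width for training
// convolutional networks.  sgemm comes from the BLAS R itself links.
extern "C" void sgemm_(const char *transa, const char *transb,
                       const int *m, const int *n, const int *k,
                       const float *alpha, const float *a, const int *lda,
                       const float *b, const int *ldb, const float *beta,
                       float *c, const int *ldc);

static std::vector<float> g_cols, g_tmp, g_wf, g_gf, g_yf;

static void to_float(const double *src, size_t n, std::vector<float> &dst) {
  dst.resize(n);
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

static void im2col_fill(const double *xp, int C, int H, int W, int N,
                        int kh, int kw, int sh, int sw, int ph, int pw,
                        float *cp) {
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  const int K = C * kh * kw;
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (size_t)n * C * H * W;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        float *col = cp + (size_t)K * (oy + (size_t)oh * (ox + (size_t)ow * n));
        for (int kx = 0; kx < kw; ++kx) {
          int ix = ox * sw - pw + kx;
          for (int ky = 0; ky < kh; ++ky) {
            int iy = oy * sh - ph + ky;
            float *dst = col + C * (ky + kh * kx);
            if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
              const double *src = xn + (size_t)C * (iy + (size_t)H * ix);
              for (int c = 0; c < C; ++c) dst[c] = (float)src[c];
            } else {
              std::memset(dst, 0, C * sizeof(float));
            }
          }
        }
      }
    }
  }
}

static void col2im_acc(const float *cp, int C, int H, int W, int N,
                       int kh, int kw, int sh, int sw, int ph, int pw,
                       double *xp) {
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  const int K = C * kh * kw;
  for (int n = 0; n < N; ++n) {
    double *xn = xp + (size_t)n * C * H * W;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const float *col =
            cp + (size_t)K * (oy + (size_t)oh * (ox + (size_t)ow * n));
        for (int kx = 0; kx < kw; ++kx) {
          int ix = ox * sw - pw + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            int iy = oy * sh - ph + ky;
            if (iy < 0 || iy >= H) continue;
            const float *src = col + C * (ky + kh * kx);
            double *dst = xn + (size_t)C * (iy + (size_t)H * ix);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericMatrix wm, NumericVector b,
                          int C, int H, int W, int N, int kh, int kw,
                          int s, int p) {
  const int oh = (H + 2 * p - kh) / s + 1;
  const int ow = (W + 2 * p - kw) / s + 1;
  const int K = C * kh * kw;
  const int M = oh * ow * N;
  const int Cout = wm.ncol();
  g_cols.resize((size_t)K * M);
  im2col_fill(x.begin(), C, H, W, N, kh, kw, s, s, p, p, g_cols.data());
  to_float(wm.begin(), (size_t)K * Cout, g_wf);
  g_yf.resize((size_t)Cout * M);
  NumericVector y(Rcpp::no_init((R_xlen_t)Cout * M));
  const float onef = 1.0f, zerof = 0.0f;
  sgemm_("T", "N", &Cout, &M, &K, &onef, g_wf.data(), &K,
         g_cols.data(), &K, &zerof, g_yf.data(), &Cout);
  double *yp = y.begin();
  const double *bp = b.begin();
  for (int m = 0; m < M; ++m)
    for (int c = 0; c < Cout; ++c)
      yp[(size_t)m * Cout + c] = (double)g_yf[(size_t)m * Cout + c] + bp[c];
  y.attr("dim") = IntegerVector::create(Cout, oh, ow, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericMatrix wm, NumericVector gy,
                 int C, int H, int W, int N, int kh, int kw, int s, int p,
                 bool need_dx, bool need_dw = true) {
  const int oh = (H + 2 * p - kh) / s + 1;
  const int ow = (W + 2 * p - kw) / s + 1;
  const int K = C * kh * kw;
  const int M = oh * ow * N;
  const int Cout = wm.ncol();
  to_float(gy.begin(), (size_t)Cout * M, g_gf);
  const float onef = 1.0f, zerof = 0.0f;
  NumericMatrix dw;
  NumericVector db;
  if (need_dw) {
    g_cols.resize((size_t)K * M);
    im2col_fill(x.begin(), C, H, W, N, kh, kw, s, s, p, p, g_cols.data());
    dw = NumericMatrix(Rcpp::no_init(K, Cout));
    g_yf.resize((size_t)K * Cout);
    sgemm_("N", "T", &K, &Cout, &M, &onef, g_cols.data(), &K,
           g_gf.data(), &Cout, &zerof, g_yf.data(), &K);
    for (size_t i = 0; i < (size_t)K * Cout; ++i) dw.begin()[i] = g_yf[i];
    db = NumericVector(Cout);
    const double *gp = gy.begin();
    for (int m = 0; m < M; ++m)
      for (int c = 0; c < Cout; ++c) db[c] += gp[(size_t)m * Cout + c];
  }
  NumericVector dx;
  if (need_dx) {
    g_tmp.resize((size_t)K * M);
    to_float(wm.begin(), (size_t)K * Cout, g_wf);
    sgemm_("N", "N", &K, &M, &Cout, &onef, g_wf.data(), &K,
           g_gf.data(), &Cout, &zerof, g_tmp.data(), &K);
    dx = NumericVector((R_xlen_t)C * H * W * N);
    col2im_acc(g_tmp.data(), C, H, W, N, kh, kw, s, s, p, p, dx.begin());
  }
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// Transposed convolution: x [Cin,h,w,N] -> y [Cout,oh,ow,N] with
// oh = (h-1)*s - 2p + kh + op.  Weight matrix [K x Cin], K = Cout*kh*kw.
// [[Rcpp::export]]
NumericVector cpp_convT_fw(NumericVector x, NumericMatrix wm, NumericVector b,
                           int Cin, int h, int w, int N, int Cout,
                           int kh, int kw, int s, int p, int op) {
  const int oh = (h - 1) * s - 2 * p + kh + op;
  const int ow = (w - 1) * s - 2 * p + kw + op;
  const int K = Cout * kh * kw;
  const int Mx = h * w * N;
  g_tmp.resize((size_t)K * Mx);
  to_float(wm.begin(), (size_t)K * Cin, g_wf);
  to_float(x.begin(), (size_t)Cin * Mx, g_gf);
  const float onef = 1.0f, zerof = 0.0f;
  sgemm_("N", "N", &K, &Mx, &Cin, &onef, g_wf.data(), &K,
         g_gf.data(), &Cin, &zerof, g_tmp.data(), &K);
  NumericVector y((R_xlen_t)Cout * oh * ow * N);
  col2im_acc(g_tmp.data(), Cout, oh, ow, N, kh, kw, s, s, p, p, y.begin());
  double *yp = y.begin();
  const double *bp = b.begin();
  const size_t sp = (size_t)oh * ow;
  for (int n = 0; n < N; ++n)
    for (size_t m = 0; m < sp; ++m)
      for (int c = 0; c < Cout; ++c)
        yp[((size_t)n * sp + m) * Cout + c] += bp[c];
  y.attr("dim") = IntegerVector::create(Cout, oh, ow, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convT_bw(NumericVector x, NumericMatrix wm, NumericVector gy,
                  int Cin, int h, int w, int N, int Cout,
                  int kh, int kw, int s, int p, int op, bool need_dx,
                  bool need_dw = true) {
  const int oh = (h - 1) * s - 2 * p + kh + op;
  const int ow = (w - 1) * s - 2 * p + kw + op;
  const int K = Cout * kh * kw;
  const int Mx = h * w * N;
  g_cols.resize((size_t)K * Mx);
  im2col_fill(gy.begin(), Cout, oh, ow, N, kh, kw, s, s, p, p, g_cols.data());
  const float onef = 1.0f, zerof = 0.0f;
  NumericMatrix dw;
  NumericVector db;
  if (need_dw) {
    to_float(x.begin(), (size_t)Cin * Mx, g_gf);
    dw = NumericMatrix(Rcpp::no_init(K, Cin));
    g_yf.resize((size_t)K * Cin);
    sgemm_("N", "T", &K, &Cin, &Mx, &onef, g_cols.data(), &K,
           g_gf.data(), &Cin, &zerof, g_yf.data(), &K);
    for (size_t i = 0; i < (size_t)K * Cin; ++i) dw.begin()[i] = g_yf[i];
    db = NumericVector(Cout);
    const double *gp = gy.begin();
    const size_t My = (size_t)oh * ow * N;
    for (size_t m = 0; m < My; ++m)
      for (int c = 0; c < Cout; ++c) db[c] += gp[m * Cout + c];
  }
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(Rcpp::no_init((R_xlen_t)Cin * Mx));
    to_float(wm.begin(), (size_t)K * Cin, g_wf);
    g_tmp.resize((size_t)Cin * Mx);
    sgemm_("T", "N", &Cin, &Mx, &K, &onef, g_wf.data(), &K,
           g_cols.data(), &K, &zerof, g_tmp.data(), &Cin);
    for (size_t i = 0; i < (size_t)Cin * Mx; ++i) dx.begin()[i] = g_tmp[i];
  }
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}
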