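#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensor layout throughout: column-major array [C, H, W, N] (channel fastest).
// Weight layout: [Cin, kh, kw, Cout]; the first three dims flatten to the
// im2col row index, so convolution is a single GEMM done in R with BLAS.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  const int K = C * kh * kw;
  NumericMatrix cols(Rcpp::no_init(K, oh * ow * N));
  const double *xp = x.begin();
  double *cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (size_t)n * C * H * W;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        double *col = cp + (size_t)K * (oy + (size_t)oh * (ox + (size_t)ow * n));
        for (int kx = 0; kx < kw; ++kx) {
          int ix = ox * sw - pw + kx;
          for (int ky = 0; ky < kh; ++ky) {
            int iy = oy * sh - ph + ky;
            double *dst = col + C * (ky + kh * kx);
            if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
              std::memcpy(dst, xn + (size_t)C * (iy + (size_t)H * ix),
                          C * sizeof(double));
            } else {
              std::memset(dst, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  const int K = C * kh * kw;
  NumericVector x((size_t)C * H * W * N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    double *xn = xp + (size_t)n * C * H * W;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const double *col =
            cp + (size_t)K * (oy + (size_t)oh * (ox + (size_t)ow * n));
        for (int kx = 0; kx < kw; ++kx) {
          int ix = ox * sw - pw + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            int iy = oy * sh - ph + ky;
            if (iy < 0 || iy >= H) continue;
            const double *src = col + C * (ky + kh * kx);
            double *dst = xn + (size_t)C * (iy + (size_t)H * ix);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2 (floor division of odd sizes drops the last
// row/column, matching the architecture conventions used in the package).
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, int C, int H, int W, int N) {
  const int oh = H / 2, ow = W / 2;
  NumericVector y((size_t)C * oh * ow * N);
  IntegerVector idx((size_t)C * oh * ow * N);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        for (int c = 0; c < C; ++c) {
          double best = -1e300;
          size_t besti = 0;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              size_t li = xoff + c + (size_t)C * ((2 * oy + dy) +
                           (size_t)H * (2 * ox + dx));
              if (xp[li] > best) { best = xp[li]; besti = li; }
            }
          }
          size_t o = (size_t)n * C * oh * ow + c + (size_t)C * (oy + (size_t)oh * ox);
          yp[o] = best;
          ip[o] = (int)besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dy, IntegerVector idx, R_xlen_t n_in) {
  NumericVector dx(n_in);
  double *dp = dx.begin();
  const double *gp = dy.begin();
  const int *ip = idx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dp[ip[i]] += gp[i];
  return dx;
}

// Bilinear warp of a single-channel image under a 2x3 affine map acting on
// normalized coordinates (corner pixels at +/-1, x horizontal, y vertical).
// The map sends output (target) coordinates to input (source) coordinates;
// samples falling outside the source frame contribute 0.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix A,
                                int oh, int ow) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  for (int j = 0; j < ow; ++j) {
    double xt = (ow == 1) ? 0.0 : -1.0 + 2.0 * j / (ow - 1);
    for (int i = 0; i < oh; ++i) {
      double yt = (oh == 1) ? 0.0 : -1.0 + 2.0 * i / (oh - 1);
      double xs = a11 * xt + a12 * yt + a13;
      double ys = a21 * xt + a22 * yt + a23;
      // to 0-based source pixel coordinates
      double js = (xs + 1.0) * (W - 1) / 2.0;
      double is = (ys + 1.0) * (H - 1) / 2.0;
      int j0 = (int)std::floor(js), i0 = (int)std::floor(is);
      double fj = js - j0, fi = is - i0;
      double acc = 0.0;
      for (int dj = 0; dj <= 1; ++dj) {
        for (int di = 0; di <= 1; ++di) {
          int jj = j0 + dj, ii = i0 + di;
          if (jj < 0 || jj >= W || ii < 0 || ii >= H) continue;
          double wgt = (dj ? fj : 1.0 - fj) * (di ? fi : 1.0 - fi);
          acc += wgt * img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Nearest-neighbour x2 upsampling (used on feedback paths to undo pooling).
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x, int C, int H, int W, int N) {
  const int oh = 2 * H, ow = 2 * W;
  NumericVector y((size_t)C * oh * ow * N);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy) {
        const double *src = xp + (size_t)n * C * H * W +
                            (size_t)C * ((oy / 2) + (size_t)H * (ox / 2));
        double *dst = yp + (size_t)n * C * oh * ow +
                      (size_t)C * (oy + (size_t)oh * ox);
        std::memcpy(dst, src, C * sizeof(double));
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy, int C, int H, int W, int N) {
  // H, W are the *input* (pre-upsampling) sizes
  const int oh = 2 * H, ow = 2 * W;
  NumericVector dx((size_t)C * H * W * N);
  const double *gp = dy.begin();
  double *dp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy) {
        const double *src = gp + (size_t)n * C * oh * ow +
                            (size_t)C * (oy + (size_t)oh * ox);
        double *dst = dp + (size_t)n * C * H * W +
                      (size_t)C * ((oy / 2) + (size_t)H * (ox / 2));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  return dx;
}

// Fused (Conv)LSTM cell.  z holds the four gate pre-activations stacked
// channelwise [4C x R] (R = spatial x batch for ConvLSTM, batch for LSTM),
// gate order (input, forget, cell, output).  Returns h, c and the gate
// activations needed for the backward pass.
// [[Rcpp::export]]
List cpp_lstm_cell_fw(NumericVector z, NumericVector c_prev, int C, int R) {
  NumericVector h(Rcpp::no_init(C * (R_xlen_t)R)), cn(Rcpp::no_init(C * (R_xlen_t)R));
  NumericVector gates(Rcpp::no_init(4 * C * (R_xlen_t)R));
  const double *zp = z.begin(), *cp = c_prev.begin();
  double *hp = h.begin(), *cnp = cn.begin(), *gp = gates.begin();
  for (R_xlen_t r = 0; r < R; ++r) {
    const double *zr = zp + 4 * (R_xlen_t)C * r;
    double *gr = gp + 4 * (R_xlen_t)C * r;
    for (int c = 0; c < C; ++c) {
      double i = 1.0 / (1.0 + std::exp(-zr[c]));
      double f = 1.0 / (1.0 + std::exp(-zr[C + c]));
      double g = std::tanh(zr[2 * C + c]);
      double o = 1.0 / (1.0 + std::exp(-zr[3 * C + c]));
      double cv = f * cp[C * r + c] + i * g;
      gr[c] = i; gr[C + c] = f; gr[2 * C + c] = g; gr[3 * C + c] = o;
      cnp[C * r + c] = cv;
      hp[C * r + c] = o * std::tanh(cv);
    }
  }
  return List::create(_["h"] = h, _["c"] = cn, _["gates"] = gates);
}

// [[Rcpp::export]]
List cpp_lstm_cell_bw(NumericVector gh, NumericVector gc,
                      NumericVector gates, NumericVector c_prev,
                      NumericVector c_new, int C, int R) {
  NumericVector dz(Rcpp::no_init(4 * C * (R_xlen_t)R));
  NumericVector dcp(Rcpp::no_init(C * (R_xlen_t)R));
  const double *ghp = gh.size() ? gh.begin() : nullptr;
  const double *gcp = gc.size() ? gc.begin() : nullptr;
  const double *gp = gates.begin(), *cpp_ = c_prev.begin(), *cnp = c_new.begin();
  double *dzp = dz.begin(), *dcpp = dcp.begin();
  for (R_xlen_t r = 0; r < R; ++r) {
    const double *gr = gp + 4 * (R_xlen_t)C * r;
    double *dzr = dzp + 4 * (R_xlen_t)C * r;
    for (int c = 0; c < C; ++c) {
      double i = gr[c], f = gr[C + c], g = gr[2 * C + c], o = gr[3 * C + c];
      double cv = cnp[C * r + c];
      double tc = std::tanh(cv);
      double dh = ghp ? ghp[C * r + c] : 0.0;
      double dc = (gcp ? gcp[C * r + c] : 0.0) + dh * o * (1.0 - tc * tc);
      double dov = dh * tc;
      double di = dc * g, dg = dc * i, df = dc * cpp_[C * r + c];
      dcpp[C * r + c] = dc * f;
      dzr[c] = di * i * (1.0 - i);
      dzr[C + c] = df * f * (1.0 - f);
      dzr[2 * C + c] = dg * (1.0 - g * g);
      dzr[3 * C + c] = dov * o * (1.0 - o);
    }
  }
  return List::create(_["dz"] = dz, _["dc_prev"] = dcp);
}
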