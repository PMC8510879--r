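// Dense numeric kernels for the CNN engine and image resampling.
// Conventions (fixed package-wide):
//   - feature tensors are R arrays dim (H, W, C, N), column-major
//   - conv weights are (3, 3, Cin, Cout); 3x3, stride 1, zero padding 1
//   - interpolation is clamp-to-edge; bilinear resize uses half-pixel centers;
//     physical-grid resampling aligns voxel-0 centers of the two grids
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// x: one sample, H*W*C doubles; out: (H*W) x (9*C), column j = (ky+1)+3*(kx+1)+9*c
static void im2col3(const double* x, int H, int W, int C, arma::mat& out) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int j = (ky + 1) + 3 * (kx + 1) + 9 * c;
        double* o = out.colptr(j);
        for (int col = 0; col < W; ++col) {
          int sc = col + kx;
          double* dst = o + (size_t)col * H;
          if (sc < 0 || sc >= W) { std::fill(dst, dst + H, 0.0); continue; }
          const double* src = xc + (size_t)sc * H;
          int r0 = std::max(0, -ky), r1 = std::min(H, H - ky);
          if (r0 > 0) std::fill(dst, dst + r0, 0.0);
          if (r1 > r0) std::copy(src + r0 + ky, src + r1 + ky, dst + r0);
          if (r1 < H) std::fill(dst + r1, dst + H, 0.0);
        }
      }
    }
  }
}

// scatter-add transpose of im2col3
static void col2im3(const arma::mat& dcol, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int j = (ky + 1) + 3 * (kx + 1) + 9 * c;
        const double* o = dcol.colptr(j);
        for (int col = 0; col < W; ++col) {
          int sc = col + kx;
          if (sc < 0 || sc >= W) continue;
          double* dst = xc + (size_t)sc * H;
          const double* src = o + (size_t)col * H;
          int r0 = std::max(0, -ky), r1 = std::min(H, H - ky);
          for (int r = r0; r < r1; ++r) dst[r + ky] += src[r];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dmx = x.attr("dim"), dmw = w.attr("dim");
  int H = dmx[0], W = dmx[1], C = dmx[2], N = dmx[3], Cout = dmw[3];
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat Xc(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, Xc);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false, true);
    Y = Xc * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dmx = x.attr("dim"), dmw = w.attr("dim");
  int H = dmx[0], W = dmx[1], C = dmx[2], N = dmx[3], Cout = dmw[3];
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  NumericVector dxv = alloc4(H, W, C, N);
  NumericVector dwv = alloc4(3, 3, C, Cout);
  NumericVector dbv(Cout);
  arma::mat dWm(dwv.begin(), 9 * C, Cout, false, true);
  arma::rowvec db(dbv.begin(), Cout, false, true);
  arma::mat Xc(H * W, 9 * C), dXc(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, Xc);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * H * W * Cout,
                 H * W, Cout, false, true);
    dWm += Xc.t() * dY;
    db += arma::sum(dY, 0);
    dXc = dY * Wm.t();
    col2im3(dXc, H, W, C, dxv.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2; idx records the 0-based offset of the argmax in x
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector dmx = x.attr("dim");
  int H = dmx[0], W = dmx[1], C = dmx[2], N = dmx[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int q = 0; q < C * N; ++q) {
    size_t xo = (size_t)q * H * W, yo = (size_t)q * Ho * Wo;
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        size_t base = xo + (size_t)(2 * c) * H + 2 * r;
        size_t best = base;
        double bv = xp[base];
        if (xp[base + 1] > bv) { bv = xp[base + 1]; best = base + 1; }
        if (xp[base + H] > bv) { bv = xp[base + H]; best = base + H; }
        if (xp[base + H + 1] > bv) { bv = xp[base + H + 1]; best = base + H + 1; }
        yp[yo + (size_t)c * Ho + r] = bv;
        ip[yo + (size_t)c * Ho + r] = (int)best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(IntegerVector idx, NumericVector dy, IntegerVector dim_x) {
  NumericVector dx = alloc4(dim_x[0], dim_x[1], dim_x[2], dim_x[3]);
  const int* ip = idx.begin();
  const double* dp = dy.begin();
  double* xp = dx.begin();
  R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ip[i]] += dp[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector dmx = x.attr("dim");
  int H = dmx[0], W = dmx[1], C = dmx[2], N = dmx[3];
  NumericVector y = alloc4(2 * H, 2 * W, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int q = 0; q < C * N; ++q) {
    size_t xo = (size_t)q * H * W, yo = (size_t)q * 4 * H * W;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double v = xp[xo + (size_t)c * H + r];
        size_t b = yo + (size_t)(2 * c) * 2 * H + 2 * r;
        yp[b] = v; yp[b + 1] = v; yp[b + 2 * H] = v; yp[b + 2 * H + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy) {
  IntegerVector dmy = dy.attr("dim");
  int H2 = dmy[0], W2 = dmy[1], C = dmy[2], N = dmy[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx = alloc4(H, W, C, N);
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int q = 0; q < C * N; ++q) {
    size_t xo = (size_t)q * H * W, yo = (size_t)q * H2 * W2;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        size_t b = yo + (size_t)(2 * c) * H2 + 2 * r;
        xp[xo + (size_t)c * H + r] = dp[b] + dp[b + 1] + dp[b + H2] + dp[b + H2 + 1];
      }
    }
  }
  return dx;
}

// bilinear resize of a single matrix, half-pixel centers, clamp-to-edge
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int out_h, int out_w) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(out_h, out_w);
  double sr = (double)H / out_h, sc = (double)W / out_w;
  for (int c = 0; c < out_w; ++c) {
    double fc = (c + 0.5) * sc - 0.5;
    int c0 = (int)std::floor(fc);
    double wc = fc - c0;
    int c0c = std::min(std::max(c0, 0), W - 1);
    int c1c = std::min(std::max(c0 + 1, 0), W - 1);
    for (int r = 0; r < out_h; ++r) {
      double fr = (r + 0.5) * sr - 0.5;
      int r0 = (int)std::floor(fr);
      double wr = fr - r0;
      int r0c = std::min(std::max(r0, 0), H - 1);
      int r1c = std::min(std::max(r0 + 1, 0), H - 1);
      y(r, c) = (1 - wr) * ((1 - wc) * x(r0c, c0c) + wc * x(r0c, c1c)) +
                wr * ((1 - wc) * x(r1c, c0c) + wc * x(r1c, c1c));
    }
  }
  return y;
}

// trilinear resampling between physical grids sharing the voxel-0 center
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector x, NumericVector in_spacing,
                                     NumericVector out_spacing, IntegerVector out_dim) {
  IntegerVector dmx = x.attr("dim");
  int H = dmx[0], W = dmx[1], D = dmx[2];
  int Ho = out_dim[0], Wo = out_dim[1], Do = out_dim[2];
  NumericVector y(Dimension(Ho, Wo, Do));
  const double* xp = x.begin();
  double* yp = y.begin();
  double s0 = out_spacing[0] / in_spacing[0];
  double s1 = out_spacing[1] / in_spacing[1];
  double s2 = out_spacing[2] / in_spacing[2];
  for (int k = 0; k < Do; ++k) {
    double fz = k * s2;
    int z0 = (int)std::floor(fz);
    double wz = fz - z0;
    int z0c = std::min(std::max(z0, 0), D - 1), z1c = std::min(std::max(z0 + 1, 0), D - 1);
    for (int j = 0; j < Wo; ++j) {
      double fc = j * s1;
      int c0 = (int)std::floor(fc);
      double wc = fc - c0;
      int c0c = std::min(std::max(c0, 0), W - 1), c1c = std::min(std::max(c0 + 1, 0), W - 1);
      for (int i = 0; i < Ho; ++i) {
        double fr = i * s0;
        int r0 = (int)std::floor(fr);
        double wr = fr - r0;
        int r0c = std::min(std::max(r0, 0), H - 1), r1c = std::min(std::max(r0 + 1, 0), H - 1);
        #define V(r, c, z) xp[(size_t)(z) * H * W + (size_t)(c) * H + (r)]
        double v00 = (1 - wr) * V(r0c, c0c, z0c) + wr * V(r1c, c0c, z0c);
        double v10 = (1 - wr) * V(r0c, c1c, z0c) + wr * V(r1c, c1c, z0c);
        double v01 = (1 - wr) * V(r0c, c0c, z1c) + wr * V(r1c, c0c, z1c);
        double v11 = (1 - wr) * V(r0c, c1c, z1c) + wr * V(r1c, c1c, z1c);
        #undef V
        double v0 = (1 - wc) * v00 + wc * v10;
        double v1 = (1 - wc) * v01 + wc * v11;
        yp[(size_t)k * Ho * Wo + (size_t)j * Ho + i] = (1 - wz) * v0 + wz * v1;
      }
    }
  }
  return y;
}

// affine warp of an (H, W, C) stack; m maps destination (row, col) to source:
// src_r = m(0,0)*r + m(0,1)*c + m(0,2); src_c = m(1,0)*r + m(1,1)*c + m(1,2)
// bilinear = false uses nearest neighbour (for label masks)
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector x, NumericMatrix m, bool bilinear) {
  IntegerVector dmx = x.attr("dim");
  int H = dmx[0], W = dmx[1], C = dmx[2];
  NumericVector y(Dimension(H, W, C));
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double fr = m(0, 0) * r + m(0, 1) * c + m(0, 2);
      double fc = m(1, 0) * r + m(1, 1) * c + m(1, 2);
      if (bilinear) {
        int r0 = (int)std::floor(fr), c0 = (int)std::floor(fc);
        double wr = fr - r0, wc = fc - c0;
        int r0c = std::min(std::max(r0, 0), H - 1), r1c = std::min(std::max(r0 + 1, 0), H - 1);
        int c0c = std::min(std::max(c0, 0), W - 1), c1c = std::min(std::max(c0 + 1, 0), W - 1);
        for (int ch = 0; ch < C; ++ch) {
          const double* pl = xp + (size_t)ch * H * W;
          double v = (1 - wr) * ((1 - wc) * pl[(size_t)c0c * H + r0c] + wc * pl[(size_t)c1c * H + r0c]) +
                     wr * ((1 - wc) * pl[(size_t)c0c * H + r1c] + wc * pl[(size_t)c1c * H + r1c]);
          yp[(size_t)ch * H * W + (size_t)c * H + r] = v;
        }
      } else {
        int rn = std::min(std::max((int)std::lround(fr), 0), H - 1);
        int cn = std::min(std::max((int)std::lround(fc), 0), W - 1);
        for (int ch = 0; ch < C; ++ch)
          yp[(size_t)ch * H * W + (size_t)c * H + r] = xp[(size_t)ch * H * W + (size_t)cn * H + rn];
      }
    }
  }
  return y;
}
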