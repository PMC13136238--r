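// Low-level numeric kernels for the espdnet autodiff tape and image ops.
// All image tensors are arma::cube with layout (H, W, C), matching R arrays
// of dim c(H, W, C). Convolution weights are matrices of shape
// (kh*kw*Cin) x Cout with row index r = di + dj*kh + c*kh*kw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

// Pixel-major loops: writes to `col` are contiguous down each column while
// reads from x (which is small enough to stay cache-resident) are strided.
static mat im2col(const cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  const int k2 = kh * kw, HW = H * W;
  mat col(k2 * C, HW, arma::fill::zeros);
  const double* xp = x.memptr();
  double* cp = col.memptr();
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double* colcol = cp + (size_t)(i + j * H) * (k2 * C);
      for (int dj = 0; dj < kw; ++dj) {
        const int sj = j + dj - cw;
        if (sj < 0 || sj >= W) continue;
        for (int di = 0; di < kh; ++di) {
          const int si = i + di - ch;
          if (si < 0 || si >= H) continue;
          const double* xs = xp + si + (size_t)sj * H;
          double* cs = colcol + di + dj * kh;
          for (int c = 0; c < C; ++c) cs[c * k2] = xs[(size_t)c * HW];
        }
      }
    }
  }
  return col;
}

static cube col2im(const mat& gcol, int H, int W, int C, int kh, int kw) {
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  const int k2 = kh * kw, HW = H * W;
  cube gx(H, W, C, arma::fill::zeros);
  const double* cp = gcol.memptr();
  double* gp = gx.memptr();
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double* colcol = cp + (size_t)(i + j * H) * (k2 * C);
      for (int dj = 0; dj < kw; ++dj) {
        const int sj = j + dj - cw;
        if (sj < 0 || sj >= W) continue;
        for (int di = 0; di < kh; ++di) {
          const int si = i + di - ch;
          if (si < 0 || si >= H) continue;
          double* gs = gp + si + (size_t)sj * H;
          const double* cs = colcol + di + dj * kh;
          for (int c = 0; c < C; ++c) gs[(size_t)c * HW] += cs[c * k2];
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  mat col = im2col(x, kh, kw);
  mat y = w.t() * col;  // Cout x HW
  y.each_col() += b;
  cube out(H, W, w.n_cols);
  for (unsigned int c = 0; c < w.n_cols; ++c)
    out.slice(c) = arma::reshape(y.row(c), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  mat gyM(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    gyM.row(c) = arma::vectorise(gy.slice(c)).t();
  mat col = im2col(x, kh, kw);
  mat gw = col * gyM.t();
  vec gb = arma::sum(gyM, 1);
  mat gcol = w * gyM;
  cube gx = col2im(gcol, H, W, C, kh, kw);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// forward that also returns the im2col matrix for reuse in backward
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_fwdcol(const arma::cube& x, const arma::mat& w,
                             const arma::vec& b, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  mat col = im2col(x, kh, kw);
  mat y = w.t() * col;
  y.each_col() += b;
  cube out(H, W, w.n_cols);
  for (unsigned int c = 0; c < w.n_cols; ++c)
    out.slice(c) = arma::reshape(y.row(c), H, W);
  return List::create(Named("y") = out, Named("col") = col);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd_col(const arma::mat& col, const arma::mat& w,
                              const arma::cube& gy, int kh, int kw, int cin) {
  const int H = gy.n_rows, W = gy.n_cols, Cout = gy.n_slices;
  mat gyM(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    gyM.row(c) = arma::vectorise(gy.slice(c)).t();
  mat gw = col * gyM.t();
  vec gb = arma::sum(gyM, 1);
  mat gcol = w * gyM;
  cube gx = col2im(gcol, H, W, cin, kh, kw);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// ---- deformable convolution (v1: learned per-location offsets) ----
// offsets cube (H, W, 2*kh*kw): slice 2q is the row (y) offset of tap q,
// slice 2q+1 the column (x) offset, q = di + dj*kh.

static inline double bil_sample(const cube& x, double pi, double pj, int c) {
  const int H = x.n_rows, W = x.n_cols;
  if (pi <= -1.0 || pi >= H || pj <= -1.0 || pj >= W) return 0.0;
  int i0 = (int)std::floor(pi), j0 = (int)std::floor(pj);
  double ai = pi - i0, aj = pj - j0;
  double v = 0.0;
  for (int di = 0; di < 2; ++di) {
    for (int dj = 0; dj < 2; ++dj) {
      int ii = i0 + di, jj = j0 + dj;
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      double wgt = (di ? ai : 1.0 - ai) * (dj ? aj : 1.0 - aj);
      v += wgt * x(ii, jj, c);
    }
  }
  return v;
}

static mat deform_im2col(const cube& x, const cube& off, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int k2 = kh * kw, ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  mat col(k2 * C, H * W, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int n = i + j * H;
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const int q = di + dj * kh;
          double pi = i + di - ch + off(i, j, 2 * q);
          double pj = j + dj - cw + off(i, j, 2 * q + 1);
          for (int c = 0; c < C; ++c)
            col(q + c * k2, n) = bil_sample(x, pi, pj, c);
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube cpp_deform_conv(const arma::cube& x, const arma::cube& off,
                           const arma::mat& w, const arma::vec& b,
                           int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  mat col = deform_im2col(x, off, kh, kw);
  mat y = w.t() * col;
  y.each_col() += b;
  cube out(H, W, w.n_cols);
  for (unsigned int c = 0; c < w.n_cols; ++c)
    out.slice(c) = arma::reshape(y.row(c), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_deform_conv_bwd(const arma::cube& x, const arma::cube& off,
                               const arma::mat& w, const arma::cube& gy,
                               int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices, k2 = kh * kw;
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  mat gyM(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    gyM.row(c) = arma::vectorise(gy.slice(c)).t();
  mat col = deform_im2col(x, off, kh, kw);
  mat gw = col * gyM.t();
  vec gb = arma::sum(gyM, 1);
  mat gcol = w * gyM;  // (k2*C) x HW

  cube gx(H, W, C, arma::fill::zeros);
  cube goff(H, W, 2 * k2, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int n = i + j * H;
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const int q = di + dj * kh;
          double pi = i + di - ch + off(i, j, 2 * q);
          double pj = j + dj - cw + off(i, j, 2 * q + 1);
          if (pi <= -1.0 || pi >= H || pj <= -1.0 || pj >= W) continue;
          int i0 = (int)std::floor(pi), j0 = (int)std::floor(pj);
          double ai = pi - i0, aj = pj - j0;
          double gpy = 0.0, gpx = 0.0;
          for (int c = 0; c < C; ++c) {
            const double g = gcol(q + c * k2, n);
            if (g == 0.0) continue;
            double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
            bool r0 = i0 >= 0 && i0 < H, r1 = i0 + 1 >= 0 && i0 + 1 < H;
            bool c0 = j0 >= 0 && j0 < W, c1 = j0 + 1 >= 0 && j0 + 1 < W;
            if (r0 && c0) { v00 = x(i0, j0, c);         gx(i0, j0, c)         += g * (1 - ai) * (1 - aj); }
            if (r1 && c0) { v10 = x(i0 + 1, j0, c);     gx(i0 + 1, j0, c)     += g * ai * (1 - aj); }
            if (r0 && c1) { v01 = x(i0, j0 + 1, c);     gx(i0, j0 + 1, c)     += g * (1 - ai) * aj; }
            if (r1 && c1) { v11 = x(i0 + 1, j0 + 1, c); gx(i0 + 1, j0 + 1, c) += g * ai * aj; }
            gpy += g * ((v10 - v00) * (1 - aj) + (v11 - v01) * aj);
            gpx += g * ((v01 - v00) * (1 - ai) + (v11 - v10) * ai);
          }
          goff(i, j, 2 * q)     += gpy;
          goff(i, j, 2 * q + 1) += gpx;
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("goff") = goff,
                      Named("gw") = gw, Named("gb") = gb);
}

// ---- pooling / resampling ----

// [[Rcpp::export]]
arma::cube cpp_avgpool2(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                               x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices;
  cube gx(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double g = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = g; gx(2 * i + 1, 2 * j, c) = g;
        gx(2 * i, 2 * j + 1, c) = g; gx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v; out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// 2x bilinear upsampling (half-pixel centers, border-clamped), plus its
// adjoint for the backward pass.
// [[Rcpp::export]]
arma::cube cpp_upsample2_bilinear(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  auto src = [](int o, int n, int& i0, int& i1, double& w1) {
    double p = (o + 0.5) / 2.0 - 0.5;
    if (p < 0) p = 0;
    if (p > n - 1) p = n - 1;
    i0 = (int)std::floor(p);
    i1 = std::min(i0 + 1, n - 1);
    w1 = p - i0;
  };
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j) {
      int j0, j1; double wj;
      src(j, W, j0, j1, wj);
      for (int i = 0; i < 2 * H; ++i) {
        int i0, i1; double wi;
        src(i, H, i0, i1, wi);
        out(i, j, c) = (1 - wi) * (1 - wj) * x(i0, j0, c) +
                       wi * (1 - wj) * x(i1, j0, c) +
                       (1 - wi) * wj * x(i0, j1, c) +
                       wi * wj * x(i1, j1, c);
      }
    }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bilinear_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C, arma::fill::zeros);
  auto src = [](int o, int n, int& i0, int& i1, double& w1) {
    double p = (o + 0.5) / 2.0 - 0.5;
    if (p < 0) p = 0;
    if (p > n - 1) p = n - 1;
    i0 = (int)std::floor(p);
    i1 = std::min(i0 + 1, n - 1);
    w1 = p - i0;
  };
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j) {
      int j0, j1; double wj;
      src(j, W, j0, j1, wj);
      for (int i = 0; i < 2 * H; ++i) {
        int i0, i1; double wi;
        src(i, H, i0, i1, wi);
        const double g = gy(i, j, c);
        gx(i0, j0, c) += (1 - wi) * (1 - wj) * g;
        gx(i1, j0, c) += wi * (1 - wj) * g;
        gx(i0, j1, c) += (1 - wi) * wj * g;
        gx(i1, j1, c) += wi * wj * g;
      }
    }
  return gx;
}

// ---- classical image operators ----

static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_sobel(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double gx = 0.0, gy = 0.0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double v = img(reflect_idx(i + di, H), reflect_idx(j + dj, W));
          // column-direction gradient (x) and row-direction gradient (y)
          const int wx = dj * (di == 0 ? 2 : 1);
          const int wy = di * (dj == 0 ? 2 : 1);
          gx += wx * v;
          gy += wy * v;
        }
      }
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += k[t + r] * img(reflect_idx(i + t, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += k[t + r] * tmp(i, reflect_idx(j + t, W));
      out(i, j) = acc;
    }
  return out;
}

// Signed Euclidean distance to the mask boundary: negative strictly inside,
// positive outside, zero on boundary pixels (foreground pixels with a
// 4-neighbour background pixel; the image border counts as background).
// [[Rcpp::export]]
NumericMatrix cpp_signed_edt(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> bi, bj;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      bool edge = (i == 0 || j == 0 || i == H - 1 || j == W - 1) ||
                  !mask(i - 1, j) || !mask(i + 1, j) ||
                  !mask(i, j - 1) || !mask(i, j + 1);
      if (edge) { bi.push_back(i); bj.push_back(j); }
    }
  NumericMatrix out(H, W);
  const int nb = bi.size();
  if (nb == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double best = R_PosInf;
      for (int t = 0; t < nb; ++t) {
        const double di = i - bi[t], dj = j - bj[t];
        const double d2 = di * di + dj * dj;
        if (d2 < best) best = d2;
      }
      const double d = std::sqrt(best);
      out(i, j) = mask(i, j) ? -d : d;
    }
  return out;
}

// Boundary pixels by 8-connectivity erosion difference (outside = background).
// Returns a 2-column matrix of 1-based (row, col) coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_pixels(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> bi, bj;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      bool boundary = false;
      for (int dj = -1; dj <= 1 && !boundary; ++dj)
        for (int di = -1; di <= 1 && !boundary; ++di) {
          if (!di && !dj) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W || !mask(ii, jj))
            boundary = true;
        }
      if (boundary) { bi.push_back(i + 1); bj.push_back(j + 1); }
    }
  IntegerMatrix out(bi.size(), 2);
  for (size_t t = 0; t < bi.size(); ++t) { out(t, 0) = bi[t]; out(t, 1) = bj[t]; }
  return out;
}

// For each row of A, the Euclidean distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(const NumericMatrix& A, const NumericMatrix& B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int a = 0; a < na; ++a) {
    double best = R_PosInf;
    for (int b = 0; b < nb; ++b) {
      const double d1 = A(a, 0) - B(b, 0), d2 = A(a, 1) - B(b, 1);
      const double d = d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// Connected component labeling, 8- or 4-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      stack.push_back({i0, j0});
      lab(i0, j0) = next;
      while (!stack.empty()) {
        auto [i, j] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            if (connectivity == 4 && di != 0 && dj != 0) continue;
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back({ii, jj});
            }
          }
      }
    }
  return lab;
}

// Inverse-mapped affine warp. m = (a11, a12, a13, a21, a22, a23) maps output
// 0-based (i, j) to input coordinates (si, sj). bilinear = FALSE -> nearest.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& img, const NumericVector& m,
                              bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double si = m[0] * i + m[1] * j + m[2];
      const double sj = m[3] * i + m[4] * j + m[5];
      if (bilinear) {
        if (si <= -1.0 || si >= H || sj <= -1.0 || sj >= W) { out(i, j) = fill; continue; }
        int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        double ai = si - i0, aj = sj - j0, v = 0.0, wsum = 0.0;
        for (int di = 0; di < 2; ++di)
          for (int dj = 0; dj < 2; ++dj) {
            const int ii = i0 + di, jj = j0 + dj;
            const double wgt = (di ? ai : 1 - ai) * (dj ? aj : 1 - aj);
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) { v += wgt * fill; }
            else { v += wgt * img(ii, jj); }
            wsum += wgt;
          }
        out(i, j) = v;
      } else {
        const int ii = (int)std::lround(si), jj = (int)std::lround(sj);
        out(i, j) = (ii < 0 || ii >= H || jj < 0 || jj >= W) ? fill : img(ii, jj);
      }
    }
  return out;
}
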