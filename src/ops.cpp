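// Low-level numerical kernels: im2col convolution (forward/backward),
// pooling, bilinear x2 resampling with adjoint, separable Gaussian blur,
// inverse-mapped affine+elastic warping, scanline polygon rasterization
// and binary-raster connectivity utilities.
//
// Array convention matches R: feature maps are H x W x C arrays (column
// major), so an R array maps onto an arma::cube with n_rows = H,
// n_cols = W, n_slices = C without copying semantics changing.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Patch element order inside a column: c + Cin*(kh + k*kw).
// Output pixel order across columns: ho + Hout*wo (column major).
static arma::mat im2col(const arma::cube& X, int k, int stride, int pad) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat col(C * k * k, (size_t)Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t p = ho + (size_t)Ho * wo;
      for (int kw = 0; kw < k; ++kw) {
        const int wi = wo * stride - pad + kw;
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const int hi = ho * stride - pad + kh;
          if (hi < 0 || hi >= H) continue;
          const int base = C * (kh + k * kw);
          for (int c = 0; c < C; ++c)
            col(base + c, p) = X(hi, wi, c);
        }
      }
    }
  }
  return col;
}

static arma::cube col2im(const arma::mat& col, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t p = ho + (size_t)Ho * wo;
      for (int kw = 0; kw < k; ++kw) {
        const int wi = wo * stride - pad + kw;
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const int hi = ho * stride - pad + kh;
          if (hi < 0 || hi >= H) continue;
          const int base = C * (kh + k * kw);
          for (int c = 0; c < C; ++c)
            X(hi, wi, c) += col(base + c, p);
        }
      }
    }
  }
  return X;
}

// Shift-and-GEMM helper for stride-1 same-size convolution: for kernel
// offset (kh, kw), copy the shifted input into a zero-padded buffer whose
// rows index output pixels (h + H*w) and columns index input channels.
static void shift_copy(const arma::mat& Xm, arma::mat& Xs, int H, int W,
                       int dh, int dw) {
  Xs.zeros();
  const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
  const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
  if (h0 >= h1 || w0 >= w1) return;
  for (int w = w0; w < w1; ++w)
    Xs.rows(w * H + h0, w * H + h1 - 1) =
      Xm.rows((w + dw) * H + h0 + dh, (w + dw) * H + h1 - 1 + dh);
}

// W has Cin*k*k rows (patch order c + Cin*(kh + k*kw)) and Cout columns.
// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, int k, int stride, int pad) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols;
  if (stride == 1 && (H + 2 * pad - k) + 1 == H &&
      (Wd + 2 * pad - k) + 1 == Wd) {
    const arma::mat Xm(const_cast<double*>(X.memptr()), (size_t)H * Wd,
                       Cin, false, true);
    arma::cube out(H, Wd, Cout);
    arma::mat Ym(out.memptr(), (size_t)H * Wd, Cout, false, true);
    Ym.zeros();
    arma::mat Xs((size_t)H * Wd, Cin);
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        shift_copy(Xm, Xs, H, Wd, kh - pad, kw - pad);
        Ym += Xs * W.rows(Cin * (kh + k * kw),
                          Cin * (kh + k * kw) + Cin - 1);
      }
    Ym.each_row() += b.t();
    return out;
  }
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  arma::mat col = im2col(X, k, stride, pad);
  arma::mat Y = W.t() * col;          // Cout x (Ho*Wo)
  Y.each_col() += b;
  arma::cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(Y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::cube& X, const arma::mat& W,
                    const arma::cube& dY, int k, int stride, int pad) {
  const int H = X.n_rows, Wd = X.n_cols, C = X.n_slices;
  const int Ho = dY.n_rows, Wo = dY.n_cols, Cout = dY.n_slices;
  if (stride == 1 && Ho == H && Wo == Wd) {
    const arma::mat Xm(const_cast<double*>(X.memptr()), (size_t)H * Wd, C,
                       false, true);
    const arma::mat dYm(const_cast<double*>(dY.memptr()), (size_t)H * Wd,
                        Cout, false, true);
    arma::mat dW(C * k * k, Cout, arma::fill::zeros);
    arma::cube dX(H, Wd, C);
    arma::mat dXm(dX.memptr(), (size_t)H * Wd, C, false, true);
    dXm.zeros();
    arma::mat Xs((size_t)H * Wd, C);
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int dh = kh - pad, dw = kw - pad;
        shift_copy(Xm, Xs, H, Wd, dh, dw);
        const int base = C * (kh + k * kw);
        dW.rows(base, base + C - 1) = Xs.t() * dYm;
        // scatter dYm * Wk' back to the shifted input positions
        arma::mat dXs = dYm * W.rows(base, base + C - 1).t();
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(Wd, Wd - dw);
        for (int w = w0; w < w1; ++w)
          dXm.rows((w + dw) * H + h0 + dh, (w + dw) * H + h1 - 1 + dh) +=
            dXs.rows(w * H + h0, w * H + h1 - 1);
      }
    arma::vec db = arma::sum(dYm, 0).t();
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  arma::mat dYm(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dYm.row(c) = arma::vectorise(dY.slice(c)).t();
  arma::mat col = im2col(X, k, stride, pad);
  arma::mat dW = col * dYm.t();       // (Cin*k*k) x Cout
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dcol = W * dYm;           // (Cin*k*k) x (Ho*Wo)
  arma::cube dX = col2im(dcol, H, Wd, C, k, stride, pad);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 3x3 max pooling, stride 2, padding 1 (the ResNet stem pool; forward only,
// the encoder is frozen).
// [[Rcpp::export]]
arma::cube maxpool3x3s2_cpp(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = (H + 2 - 3) / 2 + 1, Wo = (W + 2 - 3) / 2 + 1;
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double m = -arma::datum::inf;
        for (int kw = 0; kw < 3; ++kw) {
          const int wi = wo * 2 - 1 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            const int hi = ho * 2 - 1 + kh;
            if (hi < 0 || hi >= H) continue;
            m = std::max(m, X(hi, wi, c));
          }
        }
        out(ho, wo, c) = m;
      }
  return out;
}

// Bilinear x2 upsampling, align_corners = false convention:
// source coordinate of output index i is (i + 0.5)/2 - 0.5, clamped.
static inline void up2_coeff(int i, int n, int& i0, int& i1, double& w1) {
  double s = (i + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
arma::cube upsample2x_fwd_cpp(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1i; double ww;
      up2_coeff(wo, W, w0, w1i, ww);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1i; double wh;
        up2_coeff(ho, H, h0, h1i, wh);
        out(ho, wo, c) =
          (1 - wh) * (1 - ww) * X(h0, w0, c) + (1 - wh) * ww * X(h0, w1i, c) +
          wh * (1 - ww) * X(h1i, w0, c) + wh * ww * X(h1i, w1i, c);
      }
    }
  return out;
}

// Adjoint of upsample2x_fwd (scatter-add of interpolation weights).
// [[Rcpp::export]]
arma::cube upsample2x_bwd_cpp(const arma::cube& dY, int H, int W) {
  const int C = dY.n_slices, Ho = dY.n_rows, Wo = dY.n_cols;
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1i; double ww;
      up2_coeff(wo, W, w0, w1i, ww);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1i; double wh;
        up2_coeff(ho, H, h0, h1i, wh);
        const double g = dY(ho, wo, c);
        dX(h0, w0, c) += (1 - wh) * (1 - ww) * g;
        dX(h0, w1i, c) += (1 - wh) * ww * g;
        dX(h1i, w0, c) += wh * (1 - ww) * g;
        dX(h1i, w1i, c) += wh * ww * g;
      }
    }
  return dX;
}

// Separable Gaussian blur, kernel truncated at radius ceil(3*sigma) so the
// far field is exactly zero. border: 0 = zero padding, 1 = replicate.
// [[Rcpp::export]]
arma::mat gaussblur_cpp(const arma::mat& X, double sigma, int border) {
  if (sigma <= 0) return X;
  const int r = (int)std::ceil(3.0 * sigma);
  arma::vec ker(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    ker(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  ker /= arma::accu(ker);
  const int H = X.n_rows, W = X.n_cols;
  arma::mat tmp(H, W), out(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0;
      for (int i = -r; i <= r; ++i) {
        int hh = h + i;
        if (hh < 0 || hh >= H) {
          if (border == 0) continue;
          hh = std::min(std::max(hh, 0), H - 1);
        }
        s += ker(i + r) * X(hh, w);
      }
      tmp(h, w) = s;
    }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0;
      for (int i = -r; i <= r; ++i) {
        int ww = w + i;
        if (ww < 0 || ww >= W) {
          if (border == 0) continue;
          ww = std::min(std::max(ww, 0), W - 1);
        }
        s += ker(i + r) * tmp(h, ww);
      }
      out(h, w) = s;
    }
  return out;
}

// Inverse-mapped warp with bilinear sampling. For destination pixel centre
// (x = col, y = row; 1-based), the source location is
//   src = Ainv %*% (dst - centre - t) + centre + disp(dst)
// so identity parameters reproduce the input exactly. border: 0 = zeros,
// 1 = clamp to edge.
// [[Rcpp::export]]
arma::mat warp_cpp(const arma::mat& src, const arma::mat& Ainv,
                   double tx, double ty, double cx, double cy,
                   const arma::mat& dispx, const arma::mat& dispy,
                   int border) {
  const int H = src.n_rows, W = src.n_cols;
  const bool has_disp = dispx.n_elem == (size_t)H * W;
  arma::mat out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double dx = (c + 1) - cx - tx, dy = (r + 1) - cy - ty;
      double sx = Ainv(0, 0) * dx + Ainv(0, 1) * dy + cx;
      double sy = Ainv(1, 0) * dx + Ainv(1, 1) * dy + cy;
      if (has_disp) { sx += dispx(r, c); sy += dispy(r, c); }
      sx -= 1.0; sy -= 1.0;           // to 0-based
      double val;
      if (sx < -1 || sx > W || sy < -1 || sy > H) {
        val = 0.0;
        if (border == 1) {
          const double qx = std::min(std::max(sx, 0.0), W - 1.0);
          const double qy = std::min(std::max(sy, 0.0), H - 1.0);
          val = src((int)std::round(qy), (int)std::round(qx));
        }
        out(r, c) = val;
        continue;
      }
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      double v = 0;
      for (int j = 0; j <= 1; ++j)
        for (int i = 0; i <= 1; ++i) {
          int xx = x0 + i, yy = y0 + j;
          double wgt = (i ? fx : 1 - fx) * (j ? fy : 1 - fy);
          if (wgt == 0) continue;
          if (xx < 0 || xx >= W || yy < 0 || yy >= H) {
            if (border == 1) {
              xx = std::min(std::max(xx, 0), W - 1);
              yy = std::min(std::max(yy, 0), H - 1);
            } else continue;
          }
          v += wgt * src(yy, xx);
        }
      out(r, c) = v;
    }
  }
  return out;
}

// Warp onto a (possibly differently sized) destination grid:
//   src_coord = Ainv %*% (dst - cdst - t) + csrc + dispscale * disp(dst)
// Bilinear sampling, zero border. Identity parameters with equal grids
// reproduce the input exactly.
// [[Rcpp::export]]
arma::mat warp_grid_cpp(const arma::mat& src, int outH, int outW,
                        const arma::mat& Ainv, double tx, double ty,
                        double cdx, double cdy, double csx, double csy,
                        const arma::mat& dispx, const arma::mat& dispy,
                        double dispscale) {
  const int H = src.n_rows, W = src.n_cols;
  const bool has_disp = dispx.n_elem == (size_t)outH * outW;
  arma::mat out(outH, outW, arma::fill::zeros);
  for (int c = 0; c < outW; ++c) {
    for (int r = 0; r < outH; ++r) {
      const double dx = (c + 1) - cdx - tx, dy = (r + 1) - cdy - ty;
      double sx = Ainv(0, 0) * dx + Ainv(0, 1) * dy + csx;
      double sy = Ainv(1, 0) * dx + Ainv(1, 1) * dy + csy;
      if (has_disp) {
        sx += dispscale * dispx(r, c);
        sy += dispscale * dispy(r, c);
      }
      sx -= 1.0; sy -= 1.0;
      if (sx < -1 || sx > W || sy < -1 || sy > H) continue;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      double v = 0;
      for (int j = 0; j <= 1; ++j)
        for (int i = 0; i <= 1; ++i) {
          const int xx = x0 + i, yy = y0 + j;
          const double wgt = (i ? fx : 1 - fx) * (j ? fy : 1 - fy);
          if (wgt == 0 || xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
          v += wgt * src(yy, xx);
        }
      out(r, c) = v;
    }
  }
  return out;
}

// Even-odd scanline fill of a closed polygon given in pixel coordinates
// (x = column, y = row, both 1-based; pixel centres at integers).
// [[Rcpp::export]]
arma::mat polyfill_cpp(const arma::vec& xs, const arma::vec& ys,
                       int H, int W) {
  const int n = xs.n_elem;
  arma::mat out(H, W, arma::fill::zeros);
  std::vector<double> cross;
  for (int r = 1; r <= H; ++r) {
    const double y = (double)r;
    cross.clear();
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = ys(i), y2 = ys(j);
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        const double t = (y - y1) / (y2 - y1);
        cross.push_back(xs(i) + t * (xs(j) - xs(i)));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (size_t k = 0; k + 1 < cross.size(); k += 2) {
      int c0 = (int)std::ceil(cross[k]);
      int c1 = (int)std::floor(cross[k + 1]);
      c0 = std::max(c0, 1); c1 = std::min(c1, W);
      for (int c = c0; c <= c1; ++c) out(r - 1, c - 1) = 1.0;
    }
  }
  return out;
}

// 8-connected labelling of a binary raster; labels start at 1 in raster
// scan order (column major, matching R).
// [[Rcpp::export]]
arma::imat label8_cpp(const arma::mat& X) {
  const int H = X.n_rows, W = X.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (X(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int rr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            if (X(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              q.push(std::make_pair(r2, c2));
            }
          }
      }
    }
  return lab;
}

// Fill enclosed holes: 4-connected flood fill of the background from the
// border; any zero pixel not reached is an interior hole and becomes 1.
// [[Rcpp::export]]
arma::mat fillholes_cpp(const arma::mat& X) {
  const int H = X.n_rows, W = X.n_cols;
  arma::imat seen(H, W, arma::fill::zeros);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (r != 0 && r != H - 1 && c != 0 && c != W - 1) continue;
      if (X(r, c) == 0 && !seen(r, c)) {
        seen(r, c) = 1;
        q.push(std::make_pair(r, c));
      }
    }
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    const int r = q.front().first, c = q.front().second;
    q.pop();
    for (int k = 0; k < 4; ++k) {
      const int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      if (X(r2, c2) == 0 && !seen(r2, c2)) {
        seen(r2, c2) = 1;
        q.push(std::make_pair(r2, c2));
      }
    }
  }
  arma::mat out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = (X(r, c) != 0 || !seen(r, c)) ? 1.0 : 0.0;
  return out;
}
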