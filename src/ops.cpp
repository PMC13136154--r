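// Low-level numerical kernels for the dual-stream CNN and the image pipeline.
// Feature maps are arma::cube laid out (H, W, C), matching R arrays dim c(H,W,C).
// All coordinates here are 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col: patches of size kh x kw x Cin, stride s, zero pad p.
// Output: (kh*kw*Cin) x (OH*OW); column index = ox*OH + oy (column-major over
// the output grid); row index = c*(kh*kw) + kx*kh + ky.
static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int pad,
                        int& oh, int& ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  oh = (H + 2 * pad - kh) / stride + 1;
  ow = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols(kh * kw * C, oh * ow, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& slice = x.slice(c);
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const int col = ox * oh + oy;
        const int iy0 = oy * stride - pad, ix0 = ox * stride - pad;
        double* dst = cols.colptr(col) + c * kh * kw;
        for (int kx = 0; kx < kw; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            dst[kx * kh + ky] = slice(iy, ix);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const arma::mat& cols, int H, int W, int C, int kh, int kw,
                   int stride, int pad, arma::cube& x) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  x.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    arma::mat& slice = x.slice(c);
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const int col = ox * oh + oy;
        const int iy0 = oy * stride - pad, ix0 = ox * stride - pad;
        const double* src = cols.colptr(col) + c * kh * kw;
        for (int kx = 0; kx < kw; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            slice(iy, ix) += src[kx * kh + ky];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                    int kh, int kw, int stride, int pad) {
  int oh, ow;
  arma::mat cols = im2col(x, kh, kw, stride, pad, oh, ow);
  const int cout = w.n_cols;
  arma::mat y = cols.t() * w;               // (OH*OW) x Cout
  y.each_row() += b.t();
  arma::cube out(oh, ow, cout);
  for (int c = 0; c < cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), oh, ow);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
              int kh, int kw, int stride, int pad) {
  int oh, ow;
  arma::mat cols = im2col(x, kh, kw, stride, pad, oh, ow);
  const int cout = w.n_cols;
  arma::mat dy_mat(oh * ow, cout);
  for (int c = 0; c < cout; ++c)
    dy_mat.col(c) = arma::vectorise(dy.slice(c));
  arma::mat dw = cols * dy_mat;             // (kh*kw*Cin) x Cout
  arma::vec db = arma::sum(dy_mat, 0).t();
  arma::mat dcols = w * dy_mat.t();         // (kh*kw*Cin) x (OH*OW)
  arma::cube dx;
  col2im(dcols, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride, pad, dx);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling; records the flat index (1-based, into the HxWxC array) of each
// selected input element so the backward pass is exact.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  arma::cube y(oh, ow, C);
  arma::ucube amax(oh, ow, C);
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        double best = -arma::datum::inf;
        arma::uword bidx = 0;
        const int iy0 = oy * stride - pad, ix0 = ox * stride - pad;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            const double v = x(iy, ix, c);
            if (v > best) { best = v; bidx = (arma::uword)c * H * W + (arma::uword)ix * H + iy; }
          }
        }
        if (!std::isfinite(best)) best = 0.0;  // window fully in padding
        y(oy, ox, c) = best;
        amax(oy, ox, c) = bidx + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& dy, const arma::ucube& amax,
                       int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const arma::uword n = dy.n_elem;
  for (arma::uword i = 0; i < n; ++i) dx(amax(i) - 1) += dy(i);
  return dx;
}

// Bilinear sampling: out(i,j) = img at (row = mapy(i,j), col = mapx(i,j)),
// 0-based continuous coordinates; outside the image -> border value.
// [[Rcpp::export(name = ".warp_bilinear")]]
arma::mat warp_bilinear(const arma::mat& img, const arma::mat& mapy,
                        const arma::mat& mapx, double border) {
  const int H = img.n_rows, W = img.n_cols;
  const int OH = mapy.n_rows, OW = mapy.n_cols;
  arma::mat out(OH, OW);
  for (int j = 0; j < OW; ++j) {
    for (int i = 0; i < OH; ++i) {
      const double y = mapy(i, j), x = mapx(i, j);
      if (y < -1.0 || y > (double)H || x < -1.0 || x > (double)W) {
        out(i, j) = border; continue;
      }
      const int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
      const double fy = y - y0, fx = x - x0;
      double acc = 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          const double wx = dx ? fx : 1.0 - fx;
          const double v = (yy >= 0 && yy < H && xx >= 0 && xx < W)
                           ? img(yy, xx) : border;
          acc += wy * wx * v;
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable Gaussian blur with reflected borders; kernel radius 3*sigma.
// [[Rcpp::export(name = ".gauss_blur")]]
arma::mat gauss_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= arma::accu(k);
  const int H = img.n_rows, W = img.n_cols;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  arma::mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k(d + r) * img(reflect(i + d, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k(d + r) * tmp(i, reflect(j + d, W));
      out(i, j) = acc;
    }
  return out;
}

// Zero-mean normalized cross-correlation of a template against every offset in
// a (sub)search grid. scores(i,j) corresponds to the template's top-left at
// (y0+i-1, x0+j-1) in 1-based R coordinates.
// [[Rcpp::export(name = ".ncc_search")]]
arma::mat ncc_search(const arma::mat& img, const arma::mat& tpl,
                     int y0, int x0, int ny, int nx) {
  const int th = tpl.n_rows, tw = tpl.n_cols;
  arma::mat t = tpl - arma::accu(tpl) / tpl.n_elem;
  const double tn = std::sqrt(arma::accu(t % t));
  arma::mat scores(ny, nx, arma::fill::value(-1.0));
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      const int ry = y0 - 1 + i, rx = x0 - 1 + j;
      if (ry < 0 || rx < 0 || ry + th > (int)img.n_rows || rx + tw > (int)img.n_cols)
        continue;
      arma::mat w = img.submat(ry, rx, ry + th - 1, rx + tw - 1);
      w -= arma::accu(w) / w.n_elem;
      const double wn = std::sqrt(arma::accu(w % w));
      if (wn < 1e-12 || tn < 1e-12) { scores(i, j) = 0.0; continue; }
      scores(i, j) = arma::accu(w % t) / (wn * tn);
    }
  }
  return scores;
}
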