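// Compact CPU kernels for the network engine, image filters and the
// synthetic gland renderer. All convolutions are stride 1; "same" zero
// padding for network layers, replicate borders for image filters.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// im2col with zero padding; patch row index = di + kh*dj + kh*kw*c, matching
// the column-major flattening of an R array dim (kh, kw, Cin, Cout).
static arma::mat im2col_zero(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat cols(kh * kw * Cin, H * W, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * dj + kh * kw * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - ph;
            if (si < 0 || si >= H) continue;
            cols(r, i + H * j) = x(si, sj, c);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& Wmat,
                          const arma::vec& bias, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wmat.n_cols;
  arma::mat cols = im2col_zero(x, kh, kw);
  arma::mat out = Wmat.t() * cols;  // Cout x (H*W)
  out.each_col() += bias;
  arma::cube y(H, W, Cout);
  for (int oc = 0; oc < Cout; ++oc)
    y.slice(oc) = arma::reshape(out.row(oc).t(), H, W);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& Wmat,
                    const arma::cube& dy, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = Wmat.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat cols = im2col_zero(x, kh, kw);
  arma::mat dy_mat(Cout, H * W);
  for (int oc = 0; oc < Cout; ++oc)
    dy_mat.row(oc) = arma::vectorise(dy.slice(oc)).t();
  arma::mat dW = cols * dy_mat.t();      // (kh*kw*Cin) x Cout
  arma::vec db = arma::sum(dy_mat, 1);
  arma::mat dcols = Wmat * dy_mat;       // (kh*kw*Cin) x (H*W)
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * dj + kh * kw * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - ph;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dcols(r, i + H * j);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor semantics; idx stores the within-slice
// linear index (i + H*j) of the winner for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::cube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = si + H * sj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& idx, const arma::cube& dy,
                            int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int li = (int)idx(i, j, c);
        dx(li % H, li / H, c) += dy(i, j, c);
      }
  return dx;
}

// ---- image filters (single channel, replicate border) ----

// [[Rcpp::export]]
arma::mat cpp_filter_mean(const arma::mat& m, int k) {
  const int H = m.n_rows, W = m.n_cols, h = k / 2;
  arma::mat out(H, W);
  const double inv = 1.0 / (k * k);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di)
          s += m(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
      out(i, j) = s * inv;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_filter_median(const arma::mat& m, int k) {
  const int H = m.n_rows, W = m.n_cols, h = k / 2;
  arma::mat out(H, W);
  std::vector<double> buf(k * k);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di)
          buf[n++] = m(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];  // k*k is odd
    }
  return out;
}

// generic dense 2-D correlation with replicate border (gaussian et al.)
// [[Rcpp::export]]
arma::mat cpp_conv2_replicate(const arma::mat& m, const arma::mat& kern) {
  const int H = m.n_rows, W = m.n_cols;
  const int kh = kern.n_rows, kw = kern.n_cols;
  const int hh = kh / 2, hw = kw / 2;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          s += kern(di, dj) *
               m(clampi(i + di - hh, 0, H - 1), clampi(j + dj - hw, 0, W - 1));
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_filter_bilateral(const arma::mat& m, int k, double sigma_color,
                               double sigma_space) {
  const int H = m.n_rows, W = m.n_cols, h = k / 2;
  arma::mat out(H, W);
  const double ic = -0.5 / (sigma_color * sigma_color);
  const double is = -0.5 / (sigma_space * sigma_space);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double v0 = m(i, j);
      double s = 0.0, wsum = 0.0;
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di) {
          const double v =
              m(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
          const double dv = v - v0;
          const double w =
              std::exp((di * di + dj * dj) * is + dv * dv * ic);
          s += w * v;
          wsum += w;
        }
      out(i, j) = s / wsum;
    }
  return out;
}

// bilinear resize, half-pixel centre alignment, edge clamped
// [[Rcpp::export]]
arma::mat cpp_resize_bilinear(const arma::mat& m, int oh, int ow) {
  const int H = m.n_rows, W = m.n_cols;
  arma::mat out(oh, ow);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fx = (j + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > W - 1) fx = W - 1;
    const int x0 = (int)fx, x1 = std::min(x0 + 1, W - 1);
    const double wx = fx - x0;
    for (int i = 0; i < oh; ++i) {
      double fy = (i + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      const int y0 = (int)fy, y1 = std::min(y0 + 1, H - 1);
      const double wy = fy - y0;
      out(i, j) = (1 - wy) * ((1 - wx) * m(y0, x0) + wx * m(y0, x1)) +
                  wy * ((1 - wx) * m(y1, x0) + wx * m(y1, x1));
    }
  }
  return out;
}

// inverse-mapped affine warp: src(row,col) = A * (dst - centre) + centre + t
// bilinear sampling, replicate border
// [[Rcpp::export]]
arma::mat cpp_affine_warp(const arma::mat& m, double a11, double a12,
                          double a21, double a22, double ty, double tx) {
  const int H = m.n_rows, W = m.n_cols;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double dy = i - cy, dx = j - cx;
      double fy = a11 * dy + a12 * dx + cy + ty;
      double fx = a21 * dy + a22 * dx + cx + tx;
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      if (fx < 0) fx = 0;
      if (fx > W - 1) fx = W - 1;
      const int y0 = (int)fy, y1 = std::min(y0 + 1, H - 1);
      const int x0 = (int)fx, x1 = std::min(x0 + 1, W - 1);
      const double wy = fy - y0, wx = fx - x0;
      out(i, j) = (1 - wy) * ((1 - wx) * m(y0, x0) + wx * m(y0, x1)) +
                  wy * ((1 - wx) * m(y1, x0) + wx * m(y1, x1));
    }
  return out;
}

// ---- synthetic gland placement ----
// Greedy disk placement until the covered fraction reaches `target` without
// exceeding `upper`; proposals that would overshoot are shrunk before being
// rejected. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_place_glands(int H, int W, double target, double upper, double rmin,
                      double rmax, int max_iter) {
  arma::Mat<int> mask(H, W, arma::fill::zeros);
  long covered = 0;
  const long total = (long)H * W;
  const long target_px = (long)std::ceil(target * total);
  const long upper_px = (long)std::floor(upper * total);
  std::vector<double> cxs, cys, rs;
  for (int it = 0; it < max_iter && covered < target_px; ++it) {
    const double cy = R::runif(0.0, H - 1.0);
    const double cx = R::runif(0.0, W - 1.0);
    double r = R::runif(rmin, rmax);
    while (r >= rmin) {
      const double r2 = r * r;
      const int i0 = clampi((int)std::floor(cy - r), 0, H - 1);
      const int i1 = clampi((int)std::ceil(cy + r), 0, H - 1);
      const int j0 = clampi((int)std::floor(cx - r), 0, W - 1);
      const int j1 = clampi((int)std::ceil(cx + r), 0, W - 1);
      long add = 0;
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          const double d2 =
              (i - cy) * (i - cy) + (j - cx) * (j - cx);
          if (d2 <= r2 && mask(i, j) == 0) ++add;
        }
      if (covered + add <= upper_px) {
        if (add > 0) {
          for (int j = j0; j <= j1; ++j)
            for (int i = i0; i <= i1; ++i) {
              const double d2 =
                  (i - cy) * (i - cy) + (j - cx) * (j - cx);
              if (d2 <= r2) mask(i, j) = 1;
            }
          covered += add;
          cys.push_back(cy);
          cxs.push_back(cx);
          rs.push_back(r);
        }
        break;
      }
      r *= 0.8;  // shrink and retry so we can approach `upper` from below
    }
  }
  return List::create(_["mask"] = mask, _["coverage"] = (double)covered / total,
                      _["cy"] = cys, _["cx"] = cxs, _["r"] = rs);
}

// Rasterize glands: 0 background, 1 lumen (inner disk), 2 epithelium ring.
// Later glands overwrite earlier ones.
// [[Rcpp::export]]
arma::Mat<int> cpp_render_glands(int H, int W, NumericVector cy,
                                 NumericVector cx, NumericVector r,
                                 double lumen_frac) {
  arma::Mat<int> code(H, W, arma::fill::zeros);
  for (int g = 0; g < cy.size(); ++g) {
    const double r2 = r[g] * r[g];
    const double rl2 = (r[g] * lumen_frac) * (r[g] * lumen_frac);
    const int i0 = clampi((int)std::floor(cy[g] - r[g]), 0, H - 1);
    const int i1 = clampi((int)std::ceil(cy[g] + r[g]), 0, H - 1);
    const int j0 = clampi((int)std::floor(cx[g] - r[g]), 0, W - 1);
    const int j1 = clampi((int)std::ceil(cx[g] + r[g]), 0, W - 1);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        const double d2 =
            (i - cy[g]) * (i - cy[g]) + (j - cx[g]) * (j - cx[g]);
        if (d2 <= rl2) code(i, j) = 1;
        else if (d2 <= r2) code(i, j) = 2;
      }
  }
  return code;
}
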