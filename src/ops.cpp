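// Low-level numerical kernels for the segmentation network and the
// morphometry pipeline. All image tensors are H x W x C arma::cubes that map
// directly onto R arrays with dim c(H, W, C) (column-major, row index first).
//
// Convolution weights are stored as (k*k*Cin) x Cout matrices whose row index
// is di + k*(dj + k*ci) for kernel offset (di, dj) and input channel ci, so
// the same matrix works for the im2col GEMM in both directions.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_same(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat M(H * W, k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * ci);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            M(i + H * j, col) = x(si, sj, ci);
          }
        }
      }
    }
  }
  return M;
}

// scatter-add transpose of im2col_same
static arma::cube col2im_same(const arma::mat& M, const int H, const int W,
                              const int C, const int k) {
  const int pad = (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * ci);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            x(si, sj, ci) += M(i + H * j, col);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(rng = false)]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int F = W.n_cols;
  arma::mat out = im2col_same(x, k) * W;
  out.each_row() += b.t();
  return arma::cube(out.memptr(), H, Wd, F);
}

// [[Rcpp::export(rng = false)]]
List cpp_conv_backward(const arma::cube& x, const arma::mat& W,
                       const arma::cube& gout, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int F = gout.n_slices;
  const arma::mat M = im2col_same(x, k);
  const arma::mat G(const_cast<double*>(gout.memptr()), H * Wd, F, false);
  arma::mat gW = M.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx = col2im_same(G * W.t(), H, Wd, C, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled cube and the argmax quadrant
// (0..3, column-major within the 2x2 window) for the backward pass.
// [[Rcpp::export(rng = false)]]
List cpp_maxpool_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int q = 0;
        if (x(2 * i + 1, 2 * j, c) > best) { best = x(2 * i + 1, 2 * j, c); q = 1; }
        if (x(2 * i, 2 * j + 1, c) > best) { best = x(2 * i, 2 * j + 1, c); q = 2; }
        if (x(2 * i + 1, 2 * j + 1, c) > best) { best = x(2 * i + 1, 2 * j + 1, c); q = 3; }
        out(i, j, c) = best;
        idx(i, j, c) = q;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
arma::cube cpp_maxpool_backward(const arma::cube& gout, const arma::icube& idx) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube gx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int q = idx(i, j, c);
        gx(2 * i + (q % 2), 2 * j + (q / 2), c) = gout(i, j, c);
      }
  return gx;
}

// 2x2 stride-2 transposed convolution. Weight is a Cin x (4*Cout) matrix with
// column index q + 4*f, q = di + 2*dj the position inside the 2x2 output
// block fed by one input pixel. Non-overlapping, so forward is one GEMM plus
// a scatter.
// [[Rcpp::export(rng = false)]]
arma::cube cpp_tconv_forward(const arma::cube& x, const arma::mat& W,
                             const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int F = W.n_cols / 4;
  const arma::mat X(const_cast<double*>(x.memptr()), H * Wd, C, false);
  const arma::mat O = X * W;  // (H*W) x (4F)
  arma::cube out(2 * H, 2 * Wd, F);
  for (int f = 0; f < F; ++f)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int q = di + 2 * dj;
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            out(2 * i + di, 2 * j + dj, f) = O(i + H * j, q + 4 * f) + b(f);
      }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_tconv_backward(const arma::cube& x, const arma::mat& W,
                        const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int F = W.n_cols / 4;
  arma::mat G(H * Wd, 4 * F);
  for (int f = 0; f < F; ++f)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int q = di + 2 * dj;
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            G(i + H * j, q + 4 * f) = gout(2 * i + di, 2 * j + dj, f);
      }
  const arma::mat X(const_cast<double*>(x.memptr()), H * Wd, C, false);
  arma::mat gW = X.t() * G;
  arma::mat gXm = G * W.t();
  arma::cube gx(gXm.memptr(), H, Wd, C);
  arma::vec gb(F);
  for (int f = 0; f < F; ++f)
    gb(f) = arma::accu(gout.slice(f));
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Backward-mapping warp: out(i,j) = in(i + dr(i,j), j + dc(i,j)), bilinear
// with border clamp. Used by the elastic-deformation augmenter.
// [[Rcpp::export(rng = false)]]
arma::cube cpp_warp_bilinear(const arma::cube& img, const arma::mat& dr,
                             const arma::mat& dc) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube out(H, W, C);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double r = i + dr(i, j), c = j + dc(i, j);
      if (r < 0) r = 0;
      if (r > H - 1) r = H - 1;
      if (c < 0) c = 0;
      if (c > W - 1) c = W - 1;
      const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      const double fr = r - r0, fc = c - c0;
      for (int ch = 0; ch < C; ++ch)
        out(i, j, ch) =
          (1 - fr) * (1 - fc) * img(r0, c0, ch) + fr * (1 - fc) * img(r1, c0, ch) +
          (1 - fr) * fc * img(r0, c1, ch) + fr * fc * img(r1, c1, ch);
    }
  return out;
}

// Nearest-neighbour warp for label images (preserves binarity).
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_warp_nearest(const IntegerMatrix& mask, const arma::mat& dr,
                               const arma::mat& dc) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int r = (int)std::lround(i + dr(i, j));
      int c = (int)std::lround(j + dc(i, j));
      if (r < 0) r = 0;
      if (r > H - 1) r = H - 1;
      if (c < 0) c = 0;
      if (c > W - 1) c = W - 1;
      out(i, j) = mask(r, c);
    }
  return out;
}

// 8-connected component labelling by BFS; labels assigned in raster
// (row-major) order of first encounter, 1..n.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front(); q.pop();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}

// Moore-neighbour outer contour trace of the component with the given label.
// Returns an m x 2 matrix of 0-based (row, col) boundary coordinates in trace
// order. Terminates on re-entering the start pixel from the start direction
// (Jacob's stopping criterion).
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_trace_contour(const IntegerMatrix& lab, const int label) {
  const int H = lab.nrow(), W = lab.ncol();
  // clockwise neighbourhood starting west
  const int DR[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
  const int DC[8] = { -1, -1,  0,  1,  1,  1, 0, -1 };
  int si = -1, sj = -1;
  for (int i = 0; i < H && si < 0; ++i)
    for (int j = 0; j < W; ++j)
      if (lab(i, j) == label) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // clockwise scan for the next boundary move from (i, j) given the
  // backtrack direction; -1 when the pixel is isolated
  auto next_dir = [&](int i, int j, int back) -> int {
    for (int s = 1; s <= 8; ++s) {
      const int d = (back + s) % 8;
      const int ni = i + DR[d], nj = j + DC[d];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (lab(ni, nj) == label) return d;
    }
    return -1;
  };
  std::vector<int> rows, cols;
  const int d0 = next_dir(si, sj, 0);  // virtual entry from the west
  rows.push_back(si); cols.push_back(sj);
  if (d0 >= 0) {
    int ci = si + DR[d0], cj = sj + DC[d0];
    int back = (d0 + 4) % 8;
    const long maxit = 8L * (long)H * W + 16;
    long it = 0;
    while (it++ < maxit) {
      const int d = next_dir(ci, cj, back);
      // full circuit: back at the start about to repeat the first move
      if (ci == si && cj == sj && d == d0) break;
      rows.push_back(ci); cols.push_back(cj);
      ci += DR[d]; cj += DC[d];
      back = (d + 4) % 8;
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k];
    out(k, 1) = cols[k];
  }
  return out;
}
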