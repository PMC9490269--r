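// Low-level dense-grid kernels: interpolation (with exact adjoints, so that
// analytic loss gradients match finite differences), separable filters,
// conv-net building blocks and labeling. All grids are column-major R arrays;
// displacement fields carry their vector components in the last dimension,
// in voxel units.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------------
// Warping (linear / nearest, replicate border)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, IntegerVector dims, NumericVector u,
                       int mode) {
  const int nd = dims.size();
  if (nd == 2) {
    const int H = dims[0], W = dims[1];
    const int n = H * W;
    NumericVector out(n);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int q = i + j * H;
        double ci = clampd(i + u[q], 0.0, H - 1.0);
        double cj = clampd(j + u[q + n], 0.0, W - 1.0);
        if (mode == 1) {
          int ri = (int)std::lround(ci), rj = (int)std::lround(cj);
          out[q] = img[ri + rj * H];
        } else {
          int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj);
          if (i0 > H - 2) i0 = H - 2;
          if (j0 > W - 2) j0 = W - 2;
          if (i0 < 0) i0 = 0;
          if (j0 < 0) j0 = 0;
          double fi = ci - i0, fj = cj - j0;
          double v00 = img[i0 + j0 * H], v10 = img[i0 + 1 + j0 * H];
          double v01 = img[i0 + (j0 + 1) * H], v11 = img[i0 + 1 + (j0 + 1) * H];
          out[q] = (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
                   (1 - fi) * fj * v01 + fi * fj * v11;
        }
      }
    }
    out.attr("dim") = dims;
    return out;
  }
  const int H = dims[0], W = dims[1], D = dims[2];
  const int n = H * W * D;
  NumericVector out(n);
  for (int k = 0; k < D; ++k) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int q = i + j * H + k * H * W;
        double ci = clampd(i + u[q], 0.0, H - 1.0);
        double cj = clampd(j + u[q + n], 0.0, W - 1.0);
        double ck = clampd(k + u[q + 2 * n], 0.0, D - 1.0);
        if (mode == 1) {
          int ri = (int)std::lround(ci), rj = (int)std::lround(cj),
              rk = (int)std::lround(ck);
          out[q] = img[ri + rj * H + rk * H * W];
        } else {
          int i0 = std::min(std::max((int)std::floor(ci), 0), H - 2);
          int j0 = std::min(std::max((int)std::floor(cj), 0), W - 2);
          int k0 = std::min(std::max((int)std::floor(ck), 0), D - 2);
          if (H == 1) i0 = 0;
          if (W == 1) j0 = 0;
          if (D == 1) k0 = 0;
          double fi = ci - i0, fj = cj - j0, fk = ck - k0;
          double acc = 0.0;
          for (int dk = 0; dk <= (D > 1 ? 1 : 0); ++dk)
            for (int dj = 0; dj <= (W > 1 ? 1 : 0); ++dj)
              for (int di = 0; di <= (H > 1 ? 1 : 0); ++di) {
                double w = (di ? fi : 1 - fi) * (dj ? fj : 1 - fj) *
                           (dk ? fk : 1 - fk);
                acc += w * img[(i0 + di) + (j0 + dj) * H + (k0 + dk) * H * W];
              }
          out[q] = acc;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Linear warp together with the derivative of the interpolant w.r.t. the
// sample position (zero where the border clamp is active).
// [[Rcpp::export]]
List cpp_warp_grad(NumericVector img, IntegerVector dims, NumericVector u) {
  const int nd = dims.size();
  if (nd == 2) {
    const int H = dims[0], W = dims[1];
    const int n = H * W;
    NumericVector out(n), gr(2 * n);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int q = i + j * H;
        double pi = i + u[q], pj = j + u[q + n];
        bool cli = (pi <= 0.0 || pi >= H - 1.0);
        bool clj = (pj <= 0.0 || pj >= W - 1.0);
        double ci = clampd(pi, 0.0, H - 1.0), cj = clampd(pj, 0.0, W - 1.0);
        int i0 = std::min(std::max((int)std::floor(ci), 0), H - 2);
        int j0 = std::min(std::max((int)std::floor(cj), 0), W - 2);
        double fi = ci - i0, fj = cj - j0;
        double v00 = img[i0 + j0 * H], v10 = img[i0 + 1 + j0 * H];
        double v01 = img[i0 + (j0 + 1) * H], v11 = img[i0 + 1 + (j0 + 1) * H];
        out[q] = (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
                 (1 - fi) * fj * v01 + fi * fj * v11;
        gr[q] = cli ? 0.0 : (1 - fj) * (v10 - v00) + fj * (v11 - v01);
        gr[q + n] = clj ? 0.0 : (1 - fi) * (v01 - v00) + fi * (v11 - v10);
      }
    }
    out.attr("dim") = dims;
    IntegerVector gd = IntegerVector::create(H, W, 2);
    gr.attr("dim") = gd;
    return List::create(_["value"] = out, _["grad"] = gr);
  }
  const int H = dims[0], W = dims[1], D = dims[2];
  const int n = H * W * D;
  NumericVector out(n), gr(3 * n);
  for (int k = 0; k < D; ++k) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int q = i + j * H + k * H * W;
        double pi = i + u[q], pj = j + u[q + n], pk = k + u[q + 2 * n];
        bool cli = (pi <= 0.0 || pi >= H - 1.0);
        bool clj = (pj <= 0.0 || pj >= W - 1.0);
        bool clk = (pk <= 0.0 || pk >= D - 1.0);
        double ci = clampd(pi, 0.0, H - 1.0), cj = clampd(pj, 0.0, W - 1.0),
               ck = clampd(pk, 0.0, D - 1.0);
        int i0 = std::min(std::max((int)std::floor(ci), 0), std::max(H - 2, 0));
        int j0 = std::min(std::max((int)std::floor(cj), 0), std::max(W - 2, 0));
        int k0 = std::min(std::max((int)std::floor(ck), 0), std::max(D - 2, 0));
        double fi = ci - i0, fj = cj - j0, fk = ck - k0;
        double acc = 0, gi = 0, gj = 0, gk = 0;
        for (int dk = 0; dk <= (D > 1 ? 1 : 0); ++dk)
          for (int dj = 0; dj <= (W > 1 ? 1 : 0); ++dj)
            for (int di = 0; di <= (H > 1 ? 1 : 0); ++di) {
              double v = img[(i0 + di) + (j0 + dj) * H + (k0 + dk) * H * W];
              double wi = di ? fi : 1 - fi, wj = dj ? fj : 1 - fj,
                     wk = dk ? fk : 1 - fk;
              acc += wi * wj * wk * v;
              gi += (di ? 1.0 : -1.0) * wj * wk * v;
              gj += (dj ? 1.0 : -1.0) * wi * wk * v;
              gk += (dk ? 1.0 : -1.0) * wi * wj * v;
            }
        out[q] = acc;
        gr[q] = cli ? 0.0 : gi;
        gr[q + n] = clj ? 0.0 : gj;
        gr[q + 2 * n] = clk ? 0.0 : gk;
      }
    }
  }
  out.attr("dim") = dims;
  IntegerVector gd = IntegerVector::create(H, W, D, 3);
  gr.attr("dim") = gd;
  return List::create(_["value"] = out, _["grad"] = gr);
}

// Adjoint of the linear warp: scatter g back through the bilinear weights.
// [[Rcpp::export]]
NumericVector cpp_splat(NumericVector g, IntegerVector dims, NumericVector u) {
  const int nd = dims.size();
  if (nd == 2) {
    const int H = dims[0], W = dims[1];
    const int n = H * W;
    NumericVector out(n);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int q = i + j * H;
        double ci = clampd(i + u[q], 0.0, H - 1.0);
        double cj = clampd(j + u[q + n], 0.0, W - 1.0);
        int i0 = std::min(std::max((int)std::floor(ci), 0), H - 2);
        int j0 = std::min(std::max((int)std::floor(cj), 0), W - 2);
        double fi = ci - i0, fj = cj - j0;
        out[i0 + j0 * H] += (1 - fi) * (1 - fj) * g[q];
        out[i0 + 1 + j0 * H] += fi * (1 - fj) * g[q];
        out[i0 + (j0 + 1) * H] += (1 - fi) * fj * g[q];
        out[i0 + 1 + (j0 + 1) * H] += fi * fj * g[q];
      }
    }
    out.attr("dim") = dims;
    return out;
  }
  const int H = dims[0], W = dims[1], D = dims[2];
  const int n = H * W * D;
  NumericVector out(n);
  for (int k = 0; k < D; ++k) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int q = i + j * H + k * H * W;
        double ci = clampd(i + u[q], 0.0, H - 1.0);
        double cj = clampd(j + u[q + n], 0.0, W - 1.0);
        double ck = clampd(k + u[q + 2 * n], 0.0, D - 1.0);
        int i0 = std::min(std::max((int)std::floor(ci), 0), std::max(H - 2, 0));
        int j0 = std::min(std::max((int)std::floor(cj), 0), std::max(W - 2, 0));
        int k0 = std::min(std::max((int)std::floor(ck), 0), std::max(D - 2, 0));
        double fi = ci - i0, fj = cj - j0, fk = ck - k0;
        for (int dk = 0; dk <= (D > 1 ? 1 : 0); ++dk)
          for (int dj = 0; dj <= (W > 1 ? 1 : 0); ++dj)
            for (int di = 0; di <= (H > 1 ? 1 : 0); ++di) {
              double w = (di ? fi : 1 - fi) * (dj ? fj : 1 - fj) *
                         (dk ? fk : 1 - fk);
              out[(i0 + di) + (j0 + dj) * H + (k0 + dk) * H * W] += w * g[q];
            }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable filters
// ---------------------------------------------------------------------------

static void line_filter(const std::vector<double> &in, std::vector<double> &out,
                        const IntegerVector &dims, int axis,
                        const std::vector<double> &kern, bool replicate) {
  const int nd = dims.size();
  std::vector<int> stride(nd);
  stride[0] = 1;
  for (int a = 1; a < nd; ++a) stride[a] = stride[a - 1] * dims[a - 1];
  const int L = dims[axis], s = stride[axis];
  const int p = ((int)kern.size() - 1) / 2;
  long total = 1;
  for (int a = 0; a < nd; ++a) total *= dims[a];
  const long nlines = total / L;
  for (long ln = 0; ln < nlines; ++ln) {
    // decompose line index into base offset, skipping `axis`
    long rem = ln, base = 0;
    for (int a = 0; a < nd; ++a) {
      if (a == axis) continue;
      long idx = rem % dims[a];
      rem /= dims[a];
      base += idx * stride[a];
    }
    for (int t = 0; t < L; ++t) {
      double acc = 0.0;
      for (int m = -p; m <= p; ++m) {
        int tt = t + m;
        if (tt < 0) {
          if (!replicate) continue;
          tt = 0;
        }
        if (tt >= L) {
          if (!replicate) continue;
          tt = L - 1;
        }
        acc += kern[m + p] * in[base + (long)tt * s];
      }
      out[base + (long)t * s] = acc;
    }
  }
}

// Moving sum with odd window w along every axis, zero padding.
// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector arr, IntegerVector dims, int w) {
  long n = 1;
  for (int a = 0; a < dims.size(); ++a) n *= dims[a];
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  std::vector<double> kern(w, 1.0);
  for (int ax = 0; ax < dims.size(); ++ax) {
    line_filter(a, b, dims, ax, kern, false);
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Same 1-D kernel along the given (1-based) axes, replicate padding.
// [[Rcpp::export]]
NumericVector cpp_sepconv(NumericVector arr, IntegerVector dims,
                          NumericVector kernel, IntegerVector axes) {
  long n = 1;
  for (int a = 0; a < dims.size(); ++a) n *= dims[a];
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  std::vector<double> kern(kernel.begin(), kernel.end());
  for (int t = 0; t < axes.size(); ++t) {
    line_filter(a, b, dims, axes[t] - 1, kern, true);
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Conv-net building blocks (2-D, stride 1, zero padding)
// ---------------------------------------------------------------------------

static arma::mat im2col(const arma::cube &x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat M(C * k * k, (arma::uword)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int r = c * k * k + b * k + a;
        const int di = a - p, dj = b - p;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di;
            if (ii < 0 || ii >= H) continue;
            M(r, i + (arma::uword)j * H) = x(ii, jj, c);
          }
        }
      }
  return M;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(arma::cube x, arma::mat Wm, arma::vec b, int k) {
  const int H = x.n_rows, W = x.n_cols, K = Wm.n_rows;
  arma::mat M = im2col(x, k);
  arma::mat R = Wm * M;
  R.each_col() += b;
  arma::cube out(H, W, K);
  for (int kk = 0; kk < K; ++kk) {
    arma::rowvec row = R.row(kk);
    out.slice(kk) = arma::reshape(arma::mat(row), H, W);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(arma::cube x, arma::mat Wm, arma::cube dOut, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, K = Wm.n_rows;
  const int p = (k - 1) / 2;
  arma::mat M = im2col(x, k);
  arma::mat dOutM(K, (arma::uword)H * W);
  for (int kk = 0; kk < K; ++kk)
    dOutM.row(kk) = arma::vectorise(dOut.slice(kk)).t();
  arma::mat dW = dOutM * M.t();
  arma::vec db = arma::sum(dOutM, 1);
  arma::mat dXc = Wm.t() * dOutM; // (C k k) x (H W)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int r = c * k * k + b * k + a;
        const int di = a - p, dj = b - p;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di;
            if (ii < 0 || ii >= H) continue;
            dx(ii, jj, c) += dXc(r, i + (arma::uword)j * H);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(arma::cube x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  arma::cube y(H2, W2, C);
  IntegerVector idx(H2 * W2 * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        double best = -1e300;
        int bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) {
              best = v;
              bidx = di * 2 + dj;
            }
          }
        y(i, j, c) = best;
        idx[i + j * H2 + (long)c * H2 * W2] = bidx;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(arma::cube dy, IntegerVector idx, int H, int W) {
  const int H2 = dy.n_rows, W2 = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        int b = idx[i + j * H2 + (long)c * H2 * W2];
        dx(2 * i + b / 2, 2 * j + b % 2, c) = dy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(arma::cube x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i) y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(arma::cube dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i) dx(i / 2, j / 2, c) += dy(i, j, c);
  return dx;
}

// ---------------------------------------------------------------------------
// Connected components / distances
// ---------------------------------------------------------------------------

// BFS labeling; full=true gives 8- (2-D) / 26- (3-D) connectivity, otherwise
// face connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, bool full) {
  const int nd = dims.size();
  const int H = dims[0], W = dims[1], D = (nd == 3) ? dims[2] : 1;
  const long n = (long)H * W * D;
  IntegerVector lab(n);
  std::vector<long> stack;
  int cur = 0;
  std::vector<std::array<int, 3>> offs;
  for (int dk = (nd == 3 ? -1 : 0); dk <= (nd == 3 ? 1 : 0); ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if (!full && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1) continue;
        offs.push_back({di, dj, dk});
      }
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long q = stack.back();
      stack.pop_back();
      int i = q % H, j = (q / H) % W, k = q / ((long)H * W);
      for (size_t t = 0; t < offs.size(); ++t) {
        int ii = i + offs[t][0], jj = j + offs[t][1], kk = k + offs[t][2];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W || kk < 0 || kk >= D)
          continue;
        long qq = ii + (long)jj * H + (long)kk * H * W;
        if (mask[qq] && !lab[qq]) {
          lab[qq] = cur;
          stack.push_back(qq);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Per-row minimum squared Euclidean distance from A to B.
// [[Rcpp::export]]
NumericVector cpp_min_sqdist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int a = 0; a < d; ++a) {
        double diff = A(i, a) - B(j, a);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = best;
  }
  return out;
}
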