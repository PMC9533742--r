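// Low-level numerical kernels: im2col-based 2D convolutions (with dilation),
// partial convolutions with mask renormalisation, 2x2 max-pooling, 2x2
// stride-2 transposed convolutions, the dense-dilated (MSD) network forward
// and backward passes, 4-connected component labelling and Catmull-Rom
// bicubic resampling. Feature maps are H x W x C arrays (column-major, as R
// stores them); convolution weights are C_out x (C_in * k * k) matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::rowvec;

// Unfold a padded k x k (dilated) neighbourhood of every pixel into a
// (C*k*k) x (H*W) matrix. Zero padding keeps spatial size ("same").
static mat im2col(const cube &x, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  mat out(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int row = c * k * k + ki * k + kj;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            out(row, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto an H x W x C grid.
static cube col2im(const mat &g, const int H, const int W, const int C,
                   const int k, const int dil) {
  const int pad = dil * (k - 1) / 2;
  cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int row = c * k * k + ki * k + kj;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += g(row, j * H + i);
          }
        }
      }
    }
  }
  return out;
}

static cube mat2cube(const mat &y, const int H, const int W) {
  // y is C_out x (H*W); slice c is row c reshaped column-major.
  cube out(H, W, y.n_rows);
  for (arma::uword c = 0; c < y.n_rows; ++c) {
    out.slice(c) = arma::reshape(y.row(c), H, W);
  }
  return out;
}

static mat cube2mat(const cube &x) {
  mat out(x.n_slices, x.n_rows * x.n_cols);
  for (arma::uword c = 0; c < x.n_slices; ++c) {
    out.row(c) = arma::vectorise(x.slice(c)).t();
  }
  return out;
}

// Direct "same"-padded convolution via shifted submatrix views: for each
// kernel tap the overlapping in-bounds region of input and output is a
// single AXPY, which avoids im2col's large temporaries. Weight layout
// matches the im2col convention: column c*k*k + ki*k + kj.
struct TapRegion {
  int i0, i1, j0, j1, di, dj;  // inclusive output region + source shift
  bool empty;
};

static TapRegion tap_region(const int H, const int W, const int k,
                            const int dil, const int ki, const int kj) {
  const int pad = dil * (k - 1) / 2;
  TapRegion r;
  r.di = ki * dil - pad;
  r.dj = kj * dil - pad;
  r.i0 = std::max(0, -r.di);
  r.i1 = std::min(H - 1, H - 1 - r.di);
  r.j0 = std::max(0, -r.dj);
  r.j1 = std::min(W - 1, W - 1 - r.dj);
  r.empty = (r.i0 > r.i1) || (r.j0 > r.j1);
  return r;
}

// Convolve the first n_in slices of x into out (n_out slices), accumulating
// on top of the bias-filled out cube.
static void conv_core_fw(const cube &x, const int n_in, const mat &w,
                         const vec &b, const int k, const int dil,
                         cube &out) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_rows;
  for (int co = 0; co < Cout; ++co) out.slice(co).fill(b(co));
  for (int ci = 0; ci < n_in; ++ci) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const TapRegion r = tap_region(H, W, k, dil, ki, kj);
        if (r.empty) continue;
        const int col = ci * k * k + ki * k + kj;
        const int nr = r.i1 - r.i0 + 1;
        for (int co = 0; co < Cout; ++co) {
          const double wv = w(co, col);
          if (wv == 0) continue;
          for (int j = r.j0; j <= r.j1; ++j) {
            double *__restrict__ op = out.slice_colptr(co, j) + r.i0;
            const double *__restrict__ ip = x.slice_colptr(ci, j + r.dj) + r.i0 + r.di;
            for (int t = 0; t < nr; ++t) op[t] += wv * ip[t];
          }
        }
      }
    }
  }
}

// Accumulate input gradients (into the first n_in slices of dx) and weight
// gradients for the same convolution.
static void conv_core_bw(const cube &x, const int n_in, const mat &w,
                         const cube &dy, const int k, const int dil,
                         cube &dx, mat &dw, vec &db) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_rows;
  for (int co = 0; co < Cout; ++co) db(co) += arma::accu(dy.slice(co));
  for (int ci = 0; ci < n_in; ++ci) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const TapRegion r = tap_region(H, W, k, dil, ki, kj);
        if (r.empty) continue;
        const int col = ci * k * k + ki * k + kj;
        const int nr = r.i1 - r.i0 + 1;
        for (int co = 0; co < Cout; ++co) {
          const double wv = w(co, col);
          double acc = 0.0;
          for (int j = r.j0; j <= r.j1; ++j) {
            const double *__restrict__ dp = dy.slice_colptr(co, j) + r.i0;
            const double *__restrict__ ip = x.slice_colptr(ci, j + r.dj) + r.i0 + r.di;
            double *__restrict__ gp = dx.slice_colptr(ci, j + r.dj) + r.i0 + r.di;
            if (wv != 0) {
              for (int t = 0; t < nr; ++t) {
                acc += dp[t] * ip[t];
                gp[t] += wv * dp[t];
              }
            } else {
              for (int t = 0; t < nr; ++t) acc += dp[t] * ip[t];
            }
          }
          dw(co, col) += acc;
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube &x, const arma::mat &w,
                     const arma::vec &b, const int k, const int dil) {
  if ((int)w.n_cols != (int)x.n_slices * k * k)
    stop("weight shape does not match input channels / kernel size");
  cube out(x.n_rows, x.n_cols, w.n_rows);
  conv_core_fw(x, x.n_slices, w, b, k, dil, out);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube &x, const arma::mat &w, const arma::cube &dy,
               const int k, const int dil) {
  cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  mat dw(w.n_rows, w.n_cols, arma::fill::zeros);
  vec db(w.n_rows, arma::fill::zeros);
  conv_core_bw(x, x.n_slices, w, dy, k, dil, dx, dw, db);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Partial convolution (single-channel validity mask m, 1 = valid).
// y = (W * (x .* m)) * (k*k / sum(m in window)) + b on pixels with at least
// one valid cell in the window; 0 elsewhere. Updated mask marks those
// pixels. Out-of-frame window cells count as valid, so under a full mask
// the layer reduces exactly to a zero-padded dense convolution, borders
// included.
// [[Rcpp::export]]
List pconv2d_fw(const arma::cube &x, const arma::mat &m, const arma::mat &w,
                const arma::vec &b, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  cube mc(H, W, 1);
  mc.slice(0) = 1.0 - m;  // count in-frame invalid cells
  mat mcols = im2col(mc, k, dil);
  rowvec counts = (double)(k * k) - arma::sum(mcols, 0);
  rowvec scale(H * W, arma::fill::zeros);
  for (int p = 0; p < H * W; ++p)
    if (counts(p) > 0) scale(p) = (double)(k * k) / counts(p);
  cube xm = x;
  for (arma::uword c = 0; c < x.n_slices; ++c) xm.slice(c) %= m;
  mat y = w * im2col(xm, k, dil);
  y.each_row() %= scale;
  mat mnew(H, W, arma::fill::zeros);
  for (int p = 0; p < H * W; ++p) {
    if (counts(p) > 0) {
      mnew(p) = 1.0;
      y.col(p) += b;
    }
  }
  return List::create(_["y"] = mat2cube(y, H, W), _["mask"] = mnew,
                      _["scale"] = mat(scale));
}

// [[Rcpp::export]]
List pconv2d_bw(const arma::cube &x, const arma::mat &m, const arma::mat &scale,
                const arma::mat &w, const arma::cube &dy, const int k,
                const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  cube xm = x;
  for (arma::uword c = 0; c < x.n_slices; ++c) xm.slice(c) %= m;
  mat cols = im2col(xm, k, dil);
  mat dym = cube2mat(dy);
  rowvec sc = arma::vectorise(scale).t();
  mat dys = dym;
  dys.each_row() %= sc;
  mat dw = dys * cols.t();
  vec db(dym.n_rows, arma::fill::zeros);
  for (int p = 0; p < H * W; ++p)
    if (sc(p) > 0) db += dym.col(p);
  mat g = w.t() * dys;
  cube dx = col2im(g, H, W, x.n_slices, k, dil);
  for (arma::uword c = 0; c < dx.n_slices; ++c) dx.slice(c) %= m;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with stride 2; returns pooled map and argmax indices.
// [[Rcpp::export]]
List maxpool_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("max-pooling requires even spatial dimensions");
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  arma::ucube idx(h, w, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int b = 0; b < 2; ++b) {
          for (int a = 0; a < 2; ++a) {
            const int si = 2 * i + a, sj = 2 * j + b;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = (arma::uword)(sj * H + si); }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bw(const arma::ucube &idx, const arma::cube &dy,
                      const int H, const int W) {
  cube dx(H, W, dy.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dy.n_slices; ++c) {
    for (arma::uword j = 0; j < dy.n_cols; ++j) {
      for (arma::uword i = 0; i < dy.n_rows; ++i) {
        dx.slice(c)(idx(i, j, c)) += dy(i, j, c);
      }
    }
  }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (spatial dimension doubling).
// w is C_out x (C_in*4), inner index ci*4 + a*2 + b with (a,b) the offset
// inside the 2x2 output block.
// [[Rcpp::export]]
arma::cube upconv_fw(const arma::cube &x, const arma::mat &w,
                     const arma::vec &b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  cube y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      for (int a = 0; a < 2; ++a) {
        for (int bb = 0; bb < 2; ++bb) {
          const double wv = w(co, ci * 4 + a * 2 + bb);
          if (wv == 0) continue;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              y(2 * i + a, 2 * j + bb, co) += wv * x(i, j, ci);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv_bw(const arma::cube &x, const arma::mat &w, const arma::cube &dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  mat dw(Cout, Cin * 4, arma::fill::zeros);
  vec db(Cout, arma::fill::zeros);
  cube dx(H, W, Cin, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    db(co) = arma::accu(dy.slice(co));
    for (int ci = 0; ci < Cin; ++ci) {
      for (int a = 0; a < 2; ++a) {
        for (int bb = 0; bb < 2; ++bb) {
          double acc = 0.0;
          const double wv = w(co, ci * 4 + a * 2 + bb);
          for (int j = 0; j < W; ++j) {
            for (int i = 0; i < H; ++i) {
              const double d = dy(2 * i + a, 2 * j + bb, co);
              acc += d * x(i, j, ci);
              dx(i, j, ci) += wv * d;
            }
          }
          dw(co, ci * 4 + a * 2 + bb) = acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Nearest-neighbour 2x upsampling (used for the partial-conv mask stream).
// [[Rcpp::export]]
arma::mat upsample2_nn(const arma::mat &m) {
  mat out(2 * m.n_rows, 2 * m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) {
      const double v = m(i, j);
      out(2 * i, 2 * j) = v;
      out(2 * i + 1, 2 * j) = v;
      out(2 * i, 2 * j + 1) = v;
      out(2 * i + 1, 2 * j + 1) = v;
    }
  return out;
}

// Dense-dilated network forward pass: every layer convolves the stack of the
// input channel and all previous layer outputs (width 1) with a 3x3 kernel
// at its cycled dilation, ReLU; the output is a 1x1 convolution over the
// full stack. Returns the output and the full feature stack for backprop.
// [[Rcpp::export]]
List msd_fw(const arma::mat &x, const List &ws, const List &bs,
            const IntegerVector &dil, const arma::vec &wout,
            const double bout) {
  const int H = x.n_rows, W = x.n_cols, L = ws.size();
  cube X(H, W, L + 1);
  X.slice(0) = x;
  cube yi(H, W, 1);
  for (int i = 0; i < L; ++i) {
    mat wi = as<mat>(ws[i]);
    double bi = as<double>(bs[i]);
    conv_core_fw(X, i + 1, wi, vec{bi}, 3, dil[i], yi);
    X.slice(i + 1) = arma::clamp(yi.slice(0), 0.0, arma::datum::inf);
  }
  mat out(H, W, arma::fill::zeros);
  for (int c = 0; c <= L; ++c) out += wout(c) * X.slice(c);
  out += bout;
  return List::create(_["out"] = out, _["stack"] = X);
}

// [[Rcpp::export]]
List msd_bw(const arma::cube &X, const List &ws, const IntegerVector &dil,
            const arma::vec &wout, const arma::mat &dout) {
  const int H = X.n_rows, W = X.n_cols, L = ws.size();
  cube dX(H, W, L + 1, arma::fill::zeros);
  vec dwout(L + 1);
  for (int c = 0; c <= L; ++c) {
    dwout(c) = arma::accu(dout % X.slice(c));
    dX.slice(c) += wout(c) * dout;
  }
  const double dbout = arma::accu(dout);
  List dws(L), dbs(L);
  cube dyi(H, W, 1);
  for (int i = L - 1; i >= 0; --i) {
    // ReLU gate: slice i+1 holds post-activation values.
    dyi.slice(0) = dX.slice(i + 1) %
      arma::conv_to<mat>::from(X.slice(i + 1) > 0);
    mat wi = as<mat>(ws[i]);
    mat dwi(1, 9 * (i + 1), arma::fill::zeros);
    vec dbi(1, arma::fill::zeros);
    conv_core_bw(X, i + 1, wi, dyi, 3, dil[i], dX, dwi, dbi);
    dws[i] = dwi;
    dbs[i] = dbi(0);
  }
  return List::create(_["dws"] = dws, _["dbs"] = dbs, _["dwout"] = dwout,
                      _["dbout"] = dbout, _["dx"] = dX.slice(0));
}

// Count 4-connected components of TRUE cells.
// [[Rcpp::export]]
int label_components4(const LogicalMatrix &m) {
  const int H = m.nrow(), W = m.ncol();
  std::vector<int> lab(H * W, 0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int start = 0; start < H * W; ++start) {
    if (!m[start] || lab[start]) continue;
    ++ncomp;
    stack.push_back(start);
    lab[start] = ncomp;
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      const int i = p % H, j = p / H;
      const int ni[4] = {i - 1, i + 1, i, i};
      const int nj[4] = {j, j, j - 1, j + 1};
      for (int t = 0; t < 4; ++t) {
        if (ni[t] < 0 || ni[t] >= H || nj[t] < 0 || nj[t] >= W) continue;
        const int q = nj[t] * H + ni[t];
        if (m[q] && !lab[q]) {
          lab[q] = ncomp;
          stack.push_back(q);
        }
      }
    }
  }
  return ncomp;
}

static inline double catmull_rom(const double t, const double p0,
                                 const double p1, const double p2,
                                 const double p3) {
  return 0.5 * ((2.0 * p1) + (-p0 + p2) * t +
                (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3) * t * t +
                (-p0 + 3.0 * p1 - 3.0 * p2 + p3) * t * t * t);
}

// Separable Catmull-Rom bicubic resampling with clamped borders; pixel
// centres at half-integers so that identity size reproduces the input.
// [[Rcpp::export]]
arma::mat bicubic_resize(const arma::mat &x, const int oh, const int ow) {
  const int H = x.n_rows, W = x.n_cols;
  auto clampi = [](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };
  // horizontal pass
  mat tmp(H, ow);
  for (int j = 0; j < ow; ++j) {
    const double s = (j + 0.5) * (double)W / ow - 0.5;
    const int j1 = (int)std::floor(s);
    const double t = s - j1;
    const int j0 = clampi(j1 - 1, 0, W - 1), j1c = clampi(j1, 0, W - 1),
              j2 = clampi(j1 + 1, 0, W - 1), j3 = clampi(j1 + 2, 0, W - 1);
    for (int i = 0; i < H; ++i)
      tmp(i, j) = catmull_rom(t, x(i, j0), x(i, j1c), x(i, j2), x(i, j3));
  }
  mat out(oh, ow);
  for (int i = 0; i < oh; ++i) {
    const double s = (i + 0.5) * (double)H / oh - 0.5;
    const int i1 = (int)std::floor(s);
    const double t = s - i1;
    const int i0 = clampi(i1 - 1, 0, H - 1), i1c = clampi(i1, 0, H - 1),
              i2 = clampi(i1 + 1, 0, H - 1), i3 = clampi(i1 + 2, 0, H - 1);
    for (int j = 0; j < ow; ++j)
      out(i, j) = catmull_rom(t, tmp(i0, j), tmp(i1c, j), tmp(i2, j),
                              tmp(i3, j));
  }
  return out;
}
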