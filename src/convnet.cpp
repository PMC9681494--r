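// Minimal float32 convolution engine used by the U-Net segmentation model
// and by the topless VGG-16 / ResNet-50 feature extractors.
//
// Layout conventions (column-major, matching R arrays):
//   feature maps: cube (H, W, C)
//   conv weights: matrix (k*k*Cin, Cout), row index f = ki + k*kj + k*k*c
//   output pixel (i,j) maps to im2col row r = i + Ho*j
// All gemms run in single precision through Armadillo/BLAS.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fcube as_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  arma::fcube out(d[0], d[1], d[2]);
  const double* p = x.begin();
  float* q = out.memptr();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = static_cast<float>(p[i]);
  return out;
}

static NumericVector as_rarray(const arma::fcube& x) {
  NumericVector out(x.n_elem);
  const float* q = x.memptr();
  for (arma::uword i = 0; i < x.n_elem; ++i) out[i] = q[i];
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static arma::fmat as_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) out(i, j) = static_cast<float>(x(i, j));
  return out;
}

static NumericMatrix as_rmat(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  for (arma::uword j = 0; j < x.n_cols; ++j)
    for (arma::uword i = 0; i < x.n_rows; ++i) out(i, j) = x(i, j);
  return out;
}

// im2col: (Ho*Wo) x (k*k*Cin). Out-of-bounds taps read as `fill`.
static arma::fmat im2col(const arma::fcube& x, int k, int stride, int pad,
                         int Ho, int Wo, float fill = 0.0f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::fmat cols(Ho * (arma::uword)Wo, (arma::uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword f = ki + k * kj + (arma::uword)k * k * c;
        float* dst = cols.colptr(f);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - pad + kj;
          const bool jin = (sj >= 0 && sj < W);
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride - pad + ki;
            dst[i + (arma::uword)Ho * j] =
              (jin && si >= 0 && si < H) ? x(si, sj, c) : fill;
          }
        }
      }
    }
  }
  return cols;
}

// col2im: scatter-add transpose of im2col.
static void col2im(const arma::fmat& cols, arma::fcube& dx, int k, int stride,
                   int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword f = ki + k * kj + (arma::uword)k * k * c;
        const float* src = cols.colptr(f);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - pad + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride - pad + ki;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += src[i + (arma::uword)Ho * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cn_conv_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                          int k, int stride, int pad) {
  arma::fcube xc = as_fcube(x);
  arma::fmat Wm = as_fmat(W);
  const int Cout = Wm.n_cols;
  const int Ho = (xc.n_rows + 2 * pad - k) / stride + 1;
  const int Wo = (xc.n_cols + 2 * pad - k) / stride + 1;
  if ((int)Wm.n_rows != k * k * (int)xc.n_slices) stop("weight shape mismatch");
  arma::fmat cols = im2col(xc, k, stride, pad, Ho, Wo);
  arma::fmat y = cols * Wm;
  for (int c = 0; c < Cout; ++c) y.col(c) += static_cast<float>(b[c]);
  arma::fcube yc(y.memptr(), Ho, Wo, Cout);
  return as_rarray(yc);
}

// [[Rcpp::export]]
List cn_conv_bwd(NumericVector x, NumericMatrix W, NumericVector dy, int k,
                 int stride, int pad) {
  arma::fcube xc = as_fcube(x);
  arma::fmat Wm = as_fmat(W);
  arma::fcube dyc = as_fcube(dy);
  const int Ho = dyc.n_rows, Wo = dyc.n_cols, Cout = dyc.n_slices;
  arma::fmat dym(dyc.memptr(), (arma::uword)Ho * Wo, Cout, false);
  arma::fmat cols = im2col(xc, k, stride, pad, Ho, Wo);
  arma::fmat dW = cols.t() * dym;
  arma::fvec db = arma::sum(dym, 0).t();
  arma::fmat dcols = dym * Wm.t();
  arma::fcube dx(xc.n_rows, xc.n_cols, xc.n_slices, arma::fill::zeros);
  col2im(dcols, dx, k, stride, pad, Ho, Wo);
  NumericVector dbv(Cout);
  for (int c = 0; c < Cout; ++c) dbv[c] = db[c];
  return List::create(_["dx"] = as_rarray(dx), _["dW"] = as_rmat(dW),
                      _["db"] = dbv);
}

// [[Rcpp::export]]
List cn_maxpool_fwd(NumericVector x, int size, int stride, int pad) {
  arma::fcube xc = as_fcube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = (H + 2 * pad - size) / stride + 1;
  const int Wo = (W + 2 * pad - size) / stride + 1;
  arma::fcube y(Ho, Wo, C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        int barg = -1;
        for (int kj = 0; kj < size; ++kj) {
          const int sj = j * stride - pad + kj;
          if (sj < 0 || sj >= W) continue;
          for (int ki = 0; ki < size; ++ki) {
            const int si = i * stride - pad + ki;
            if (si < 0 || si >= H) continue;
            const float v = xc(si, sj, c);
            if (v > best) { best = v; barg = si + H * sj + H * W * c; }
          }
        }
        y(i, j, c) = best;
        idx[(R_xlen_t)(i + (R_xlen_t)Ho * j + (R_xlen_t)Ho * Wo * c)] = barg;
        ++t;
      }
    }
  }
  (void)t;
  return List::create(_["y"] = as_rarray(y), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cn_maxpool_bwd(IntegerVector idx, NumericVector dy, int H, int W,
                             int C) {
  arma::fcube dyc = as_fcube(dy);
  arma::fcube dx(H, W, C, arma::fill::zeros);
  float* p = dx.memptr();
  const float* q = dyc.memptr();
  for (R_xlen_t t = 0; t < idx.size(); ++t)
    if (idx[t] >= 0) p[idx[t]] += q[t];
  return as_rarray(dx);
}

// Transposed convolution, kernel 2x2, stride 2 (the U-Net upsampling step).
// W layout: matrix (Cin, 4*Cout); tap t = di + 2*dj owns columns
// [t*Cout, (t+1)*Cout).
// [[Rcpp::export]]
NumericVector cn_upconv_fwd(NumericVector x, NumericMatrix W, NumericVector b) {
  arma::fcube xc = as_fcube(x);
  arma::fmat Wm = as_fmat(W);
  const int Hi = xc.n_rows, Wi = xc.n_cols, Cin = xc.n_slices;
  const int Cout = Wm.n_cols / 4;
  if ((int)Wm.n_rows != Cin) stop("upconv weight shape mismatch");
  arma::fmat X(xc.memptr(), (arma::uword)Hi * Wi, Cin, false);
  arma::fcube y(2 * Hi, 2 * Wi, Cout);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    arma::fmat Yt = X * Wm.cols(t * Cout, (t + 1) * Cout - 1);
    for (int c = 0; c < Cout; ++c) {
      const float* src = Yt.colptr(c);
      for (int j = 0; j < Wi; ++j)
        for (int i = 0; i < Hi; ++i)
          y(2 * i + di, 2 * j + dj, c) = src[i + (arma::uword)Hi * j] +
            static_cast<float>(b[c]);
    }
  }
  return as_rarray(y);
}

// [[Rcpp::export]]
List cn_upconv_bwd(NumericVector x, NumericMatrix W, NumericVector dy) {
  arma::fcube xc = as_fcube(x);
  arma::fmat Wm = as_fmat(W);
  arma::fcube dyc = as_fcube(dy);
  const int Hi = xc.n_rows, Wi = xc.n_cols, Cin = xc.n_slices;
  const int Cout = Wm.n_cols / 4;
  arma::fmat X(xc.memptr(), (arma::uword)Hi * Wi, Cin, false);
  arma::fmat dX((arma::uword)Hi * Wi, Cin, arma::fill::zeros);
  arma::fmat dW(Cin, 4 * Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  arma::fmat dYt((arma::uword)Hi * Wi, Cout);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    for (int c = 0; c < Cout; ++c) {
      float* dst = dYt.colptr(c);
      for (int j = 0; j < Wi; ++j)
        for (int i = 0; i < Hi; ++i)
          dst[i + (arma::uword)Hi * j] = dyc(2 * i + di, 2 * j + dj, c);
    }
    dX += dYt * Wm.cols(t * Cout, (t + 1) * Cout - 1).t();
    dW.cols(t * Cout, (t + 1) * Cout - 1) = X.t() * dYt;
    db += arma::sum(dYt, 0).t();
  }
  arma::fcube dxc(dX.memptr(), Hi, Wi, Cin);
  NumericVector dbv(Cout);
  for (int c = 0; c < Cout; ++c) dbv[c] = db[c];
  return List::create(_["dx"] = as_rarray(dxc), _["dW"] = as_rmat(dW),
                      _["db"] = dbv);
}

// 8-connected labeling of a binary matrix (used on thin edge chains, where
// diagonal steps must stay connected).
// [[Rcpp::export]]
IntegerMatrix cn_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (mask(i0, j0) == 0 || lab(i0, j0) != 0) continue;
      lab(i0, j0) = ++next;
      q.push(i0 + H * j0);
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int i = p % H, j = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = i + di, nj = j + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(ni + H * nj);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Fill the interior of closed edge chains: flood the background 4-connected
// from the image border; pixels never reached are enclosed by an edge and
// become foreground together with the edges themselves.
// [[Rcpp::export]]
IntegerMatrix cn_fill_closed(IntegerMatrix edges) {
  const int H = edges.nrow(), W = edges.ncol();
  IntegerMatrix out(H, W);
  std::vector<char> seen((size_t)H * W, 0);
  std::queue<int> q;
  for (int i = 0; i < H; ++i) {
    for (int j : {0, W - 1}) {
      if (edges(i, j) == 0 && !seen[i + (size_t)H * j]) {
        seen[i + (size_t)H * j] = 1; q.push(i + H * j);
      }
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i : {0, H - 1}) {
      if (edges(i, j) == 0 && !seen[i + (size_t)H * j]) {
        seen[i + (size_t)H * j] = 1; q.push(i + H * j);
      }
    }
  }
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int i = p % H, j = p / H;
    for (int t = 0; t < 4; ++t) {
      const int ni = i + di[t], nj = j + dj[t];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const size_t s = ni + (size_t)H * nj;
      if (!seen[s] && edges(ni, nj) == 0) { seen[s] = 1; q.push(ni + H * nj); }
    }
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = (edges(i, j) != 0 || !seen[i + (size_t)H * j]) ? 1 : 0;
  return out;
}

// ---- batched variants ----------------------------------------------------
// A batch is an (H, W, C, B) R array, viewed here as an fcube with
// C*B slices (slice index = c + C*b). All heavy gemms amortize over the
// whole batch.

static arma::fcube as_fcube4(const NumericVector& x, int& C, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, B)");
  C = d[2]; B = d[3];
  arma::fcube out(d[0], d[1], (arma::uword)C * B);
  const double* p = x.begin();
  float* q = out.memptr();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = static_cast<float>(p[i]);
  return out;
}

static NumericVector as_rarray4(const arma::fcube& x, int C, int B) {
  NumericVector out(x.n_elem);
  const float* q = x.memptr();
  for (arma::uword i = 0; i < x.n_elem; ++i) out[i] = q[i];
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, C, B);
  return out;
}

// batched im2col: rows grouped by batch item, (B*Ho*Wo) x (k*k*C)
static arma::fmat im2col_b(const arma::fcube& x, int C, int B, int k,
                           int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols;
  const arma::uword hw = (arma::uword)Ho * Wo;
  arma::fmat cols(hw * B, (arma::uword)k * k * C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const arma::uword sl = c + (arma::uword)C * b;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const arma::uword f = ki + k * kj + (arma::uword)k * k * c;
          float* dst = cols.colptr(f) + hw * b;
          for (int j = 0; j < Wo; ++j) {
            const int sj = j * stride - pad + kj;
            const bool jin = (sj >= 0 && sj < W);
            for (int i = 0; i < Ho; ++i) {
              const int si = i * stride - pad + ki;
              dst[i + (arma::uword)Ho * j] =
                (jin && si >= 0 && si < H) ? x(si, sj, sl) : 0.0f;
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_b(const arma::fmat& cols, arma::fcube& dx, int C, int B,
                     int k, int stride, int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols;
  const arma::uword hw = (arma::uword)Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const arma::uword sl = c + (arma::uword)C * b;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const arma::uword f = ki + k * kj + (arma::uword)k * k * c;
          const float* src = cols.colptr(f) + hw * b;
          for (int j = 0; j < Wo; ++j) {
            const int sj = j * stride - pad + kj;
            if (sj < 0 || sj >= W) continue;
            for (int i = 0; i < Ho; ++i) {
              const int si = i * stride - pad + ki;
              if (si < 0 || si >= H) continue;
              dx(si, sj, sl) += src[i + (arma::uword)Ho * j];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cnb_conv_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                           int k, int stride, int pad) {
  int C, B;
  arma::fcube xc = as_fcube4(x, C, B);
  arma::fmat Wm = as_fmat(W);
  const int Cout = Wm.n_cols;
  const int Ho = (xc.n_rows + 2 * pad - k) / stride + 1;
  const int Wo = (xc.n_cols + 2 * pad - k) / stride + 1;
  arma::fmat cols = im2col_b(xc, C, B, k, stride, pad, Ho, Wo);
  arma::fmat y = cols * Wm;
  for (int c = 0; c < Cout; ++c) y.col(c) += static_cast<float>(b[c]);
  // y rows: (batch-blocked pixel) x Cout -> cube (Ho, Wo, Cout*B)
  arma::fcube yc(Ho, Wo, (arma::uword)Cout * B);
  const arma::uword hw = (arma::uword)Ho * Wo;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cout; ++c)
      std::copy(y.colptr(c) + hw * bb, y.colptr(c) + hw * (bb + 1),
                yc.slice_memptr(c + (arma::uword)Cout * bb));
  return as_rarray4(yc, Cout, B);
}

// [[Rcpp::export]]
List cnb_conv_bwd(NumericVector x, NumericMatrix W, NumericVector dy, int k,
                  int stride, int pad) {
  int C, B, Cout, B2;
  arma::fcube xc = as_fcube4(x, C, B);
  arma::fmat Wm = as_fmat(W);
  arma::fcube dyc = as_fcube4(dy, Cout, B2);
  const int Ho = dyc.n_rows, Wo = dyc.n_cols;
  const arma::uword hw = (arma::uword)Ho * Wo;
  arma::fmat dym(hw * B, Cout);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cout; ++c)
      std::copy(dyc.slice_memptr(c + (arma::uword)Cout * bb),
                dyc.slice_memptr(c + (arma::uword)Cout * bb) + hw,
                dym.colptr(c) + hw * bb);
  arma::fmat cols = im2col_b(xc, C, B, k, stride, pad, Ho, Wo);
  arma::fmat dW = cols.t() * dym;
  arma::fvec db = arma::sum(dym, 0).t();
  arma::fmat dcols = dym * Wm.t();
  arma::fcube dx(xc.n_rows, xc.n_cols, xc.n_slices, arma::fill::zeros);
  col2im_b(dcols, dx, C, B, k, stride, pad, Ho, Wo);
  NumericVector dbv(Cout);
  for (int c = 0; c < Cout; ++c) dbv[c] = db[c];
  return List::create(_["dx"] = as_rarray4(dx, C, B), _["dW"] = as_rmat(dW),
                      _["db"] = dbv);
}

// [[Rcpp::export]]
List cnb_maxpool_fwd(NumericVector x, int size, int stride, int pad) {
  int C, B;
  arma::fcube xc = as_fcube4(x, C, B);
  const int H = xc.n_rows, W = xc.n_cols;
  const int Ho = (H + 2 * pad - size) / stride + 1;
  const int Wo = (W + 2 * pad - size) / stride + 1;
  arma::fcube y(Ho, Wo, (arma::uword)C * B);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * B);
  for (arma::uword sl = 0; sl < (arma::uword)C * B; ++sl) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        int barg = -1;
        for (int kj = 0; kj < size; ++kj) {
          const int sj = j * stride - pad + kj;
          if (sj < 0 || sj >= W) continue;
          for (int ki = 0; ki < size; ++ki) {
            const int si = i * stride - pad + ki;
            if (si < 0 || si >= H) continue;
            const float v = xc(si, sj, sl);
            if (v > best) {
              best = v;
              barg = si + H * sj + (int)(H * (arma::uword)W * sl);
            }
          }
        }
        y(i, j, sl) = best;
        idx[i + (R_xlen_t)Ho * j + (R_xlen_t)Ho * Wo * sl] = barg;
      }
    }
  }
  return List::create(_["y"] = as_rarray4(y, C, B), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cnb_maxpool_bwd(IntegerVector idx, NumericVector dy, int H,
                              int W, int C, int B) {
  int Co, Bo;
  arma::fcube dyc = as_fcube4(dy, Co, Bo);
  arma::fcube dx(H, W, (arma::uword)C * B, arma::fill::zeros);
  float* p = dx.memptr();
  const float* q = dyc.memptr();
  for (R_xlen_t t = 0; t < idx.size(); ++t)
    if (idx[t] >= 0) p[idx[t]] += q[t];
  return as_rarray4(dx, C, B);
}

// [[Rcpp::export]]
NumericVector cnb_upconv_fwd(NumericVector x, NumericMatrix W,
                             NumericVector b) {
  int Cin, B;
  arma::fcube xc = as_fcube4(x, Cin, B);
  arma::fmat Wm = as_fmat(W);
  const int Hi = xc.n_rows, Wi = xc.n_cols;
  const int Cout = Wm.n_cols / 4;
  const arma::uword hw = (arma::uword)Hi * Wi;
  arma::fmat X(hw * B, Cin);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cin; ++c)
      std::copy(xc.slice_memptr(c + (arma::uword)Cin * bb),
                xc.slice_memptr(c + (arma::uword)Cin * bb) + hw,
                X.colptr(c) + hw * bb);
  arma::fcube y(2 * Hi, 2 * Wi, (arma::uword)Cout * B);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    arma::fmat Yt = X * Wm.cols(t * Cout, (t + 1) * Cout - 1);
    for (int bb = 0; bb < B; ++bb) {
      for (int c = 0; c < Cout; ++c) {
        const float* src = Yt.colptr(c) + hw * bb;
        arma::uword sl = c + (arma::uword)Cout * bb;
        for (int j = 0; j < Wi; ++j)
          for (int i = 0; i < Hi; ++i)
            y(2 * i + di, 2 * j + dj, sl) = src[i + (arma::uword)Hi * j] +
              static_cast<float>(b[c]);
      }
    }
  }
  return as_rarray4(y, Cout, B);
}

// [[Rcpp::export]]
List cnb_upconv_bwd(NumericVector x, NumericMatrix W, NumericVector dy) {
  int Cin, B, Cout, B2;
  arma::fcube xc = as_fcube4(x, Cin, B);
  arma::fmat Wm = as_fmat(W);
  arma::fcube dyc = as_fcube4(dy, Cout, B2);
  const int Hi = xc.n_rows, Wi = xc.n_cols;
  const arma::uword hw = (arma::uword)Hi * Wi;
  arma::fmat X(hw * B, Cin);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cin; ++c)
      std::copy(xc.slice_memptr(c + (arma::uword)Cin * bb),
                xc.slice_memptr(c + (arma::uword)Cin * bb) + hw,
                X.colptr(c) + hw * bb);
  arma::fmat dX(hw * B, Cin, arma::fill::zeros);
  arma::fmat dW(Cin, 4 * Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  arma::fmat dYt(hw * B, Cout);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    for (int bb = 0; bb < B; ++bb) {
      for (int c = 0; c < Cout; ++c) {
        float* dst = dYt.colptr(c) + hw * bb;
        arma::uword sl = c + (arma::uword)Cout * bb;
        for (int j = 0; j < Wi; ++j)
          for (int i = 0; i < Hi; ++i)
            dst[i + (arma::uword)Hi * j] = dyc(2 * i + di, 2 * j + dj, sl);
      }
    }
    dX += dYt * Wm.cols(t * Cout, (t + 1) * Cout - 1).t();
    dW.cols(t * Cout, (t + 1) * Cout - 1) = X.t() * dYt;
    db += arma::sum(dYt, 0).t();
  }
  arma::fcube dxc(Hi, Wi, (arma::uword)Cin * B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cin; ++c)
      std::copy(dX.colptr(c) + hw * bb, dX.colptr(c) + hw * (bb + 1),
                dxc.slice_memptr(c + (arma::uword)Cin * bb));
  NumericVector dbv(Cout);
  for (int c = 0; c < Cout; ++c) dbv[c] = db[c];
  return List::create(_["dx"] = as_rarray4(dxc, Cin, B),
                      _["dW"] = as_rmat(dW), _["db"] = dbv);
}

// ---- full U-Net step in C++ ----------------------------------------------
// One call per batch: forward, focal loss, backward, gradients. Keeping the
// whole step native avoids per-layer R<->C++ activation copies.

struct ConvPar { arma::fmat W; arma::fvec b; };

static ConvPar get_par(const List& params, const std::string& nm) {
  NumericMatrix W = params[nm + ".W"];
  NumericVector b = params[nm + ".b"];
  ConvPar c;
  c.W = as_fmat(W);
  c.b.set_size(b.size());
  for (int i = 0; i < b.size(); ++i) c.b[i] = static_cast<float>(b[i]);
  return c;
}

static arma::fcube conv_f(const arma::fcube& x, int C, int B,
                          const ConvPar& cw, int k, int stride, int pad,
                          arma::fmat* cols_out = nullptr) {
  const int Cout = cw.W.n_cols;
  const int Ho = (x.n_rows + 2 * pad - k) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - k) / stride + 1;
  arma::fmat cols = im2col_b(x, C, B, k, stride, pad, Ho, Wo);
  arma::fmat y = cols * cw.W;
  for (int c = 0; c < Cout; ++c) y.col(c) += cw.b[c];
  if (cols_out) *cols_out = std::move(cols);
  arma::fcube yc(Ho, Wo, (arma::uword)Cout * B);
  const arma::uword hw = (arma::uword)Ho * Wo;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cout; ++c)
      std::copy(y.colptr(c) + hw * bb, y.colptr(c) + hw * (bb + 1),
                yc.slice_memptr(c + (arma::uword)Cout * bb));
  return yc;
}

// dy in cube layout -> matrix (B*Ho*Wo) x Cout
static arma::fmat cube_to_mat(const arma::fcube& dyc, int Cout, int B) {
  const arma::uword hw = (arma::uword)dyc.n_rows * dyc.n_cols;
  arma::fmat dym(hw * B, Cout);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cout; ++c)
      std::copy(dyc.slice_memptr(c + (arma::uword)Cout * bb),
                dyc.slice_memptr(c + (arma::uword)Cout * bb) + hw,
                dym.colptr(c) + hw * bb);
  return dym;
}

// conv backward; x needed for dW via im2col (recomputed: cheaper than
// caching every cols matrix)
static arma::fcube conv_b(const arma::fcube& x, int C, int B,
                          const ConvPar& cw, const arma::fcube& dy, int k,
                          int stride, int pad, arma::fmat& dW,
                          arma::fvec& db,
                          const arma::fmat* cols_cached = nullptr) {
  const int Cout = cw.W.n_cols;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::fmat dym = cube_to_mat(dy, Cout, B);
  if (cols_cached) {
    dW = cols_cached->t() * dym;
  } else {
    arma::fmat cols = im2col_b(x, C, B, k, stride, pad, Ho, Wo);
    dW = cols.t() * dym;
  }
  db = arma::sum(dym, 0).t();
  arma::fmat dcols = dym * cw.W.t();
  arma::fcube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_b(dcols, dx, C, B, k, stride, pad, Ho, Wo);
  return dx;
}

static void relu_(arma::fcube& x) {
  float* p = x.memptr();
  for (arma::uword i = 0; i < x.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}

// gradient gated by the post-activation (0 where activation was clipped)
static void relu_gate(arma::fcube& g, const arma::fcube& a) {
  float* p = g.memptr();
  const float* q = a.memptr();
  for (arma::uword i = 0; i < g.n_elem; ++i) if (q[i] <= 0) p[i] = 0;
}

static arma::fcube maxpool_f(const arma::fcube& x, std::vector<int>& idx) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::fcube y(Ho, Wo, S);
  idx.assign((size_t)Ho * Wo * S, -1);
  for (int sl = 0; sl < S; ++sl) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        int barg = -1;
        for (int kj = 0; kj < 2; ++kj)
          for (int ki = 0; ki < 2; ++ki) {
            const int si = 2 * i + ki, sj = 2 * j + kj;
            const float v = x(si, sj, sl);
            if (v > best) { best = v; barg = si + H * sj + H * W * sl; }
          }
        y(i, j, sl) = best;
        idx[i + (size_t)Ho * j + (size_t)Ho * Wo * sl] = barg;
      }
    }
  }
  return y;
}

static arma::fcube maxpool_b(const std::vector<int>& idx,
                             const arma::fcube& dy, int H, int W, int S) {
  arma::fcube dx(H, W, S, arma::fill::zeros);
  float* p = dx.memptr();
  const float* q = dy.memptr();
  for (size_t t = 0; t < idx.size(); ++t)
    if (idx[t] >= 0) p[idx[t]] += q[t];
  return dx;
}

static arma::fcube upconv_f(const arma::fcube& x, int Cin, int B,
                            const ConvPar& cw) {
  const int Hi = x.n_rows, Wi = x.n_cols;
  const int Cout = cw.W.n_cols / 4;
  const arma::uword hw = (arma::uword)Hi * Wi;
  arma::fmat X = cube_to_mat(x, Cin, B);
  arma::fcube y(2 * Hi, 2 * Wi, (arma::uword)Cout * B);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    arma::fmat Yt = X * cw.W.cols(t * Cout, (t + 1) * Cout - 1);
    for (int bb = 0; bb < B; ++bb)
      for (int c = 0; c < Cout; ++c) {
        const float* src = Yt.colptr(c) + hw * bb;
        const arma::uword sl = c + (arma::uword)Cout * bb;
        for (int j = 0; j < Wi; ++j)
          for (int i = 0; i < Hi; ++i)
            y(2 * i + di, 2 * j + dj, sl) =
              src[i + (arma::uword)Hi * j] + cw.b[c];
      }
  }
  return y;
}

static arma::fcube upconv_b(const arma::fcube& x, int Cin, int B,
                            const ConvPar& cw, const arma::fcube& dy,
                            arma::fmat& dW, arma::fvec& db) {
  const int Hi = x.n_rows, Wi = x.n_cols;
  const int Cout = cw.W.n_cols / 4;
  const arma::uword hw = (arma::uword)Hi * Wi;
  arma::fmat X = cube_to_mat(x, Cin, B);
  arma::fmat dX(hw * B, Cin, arma::fill::zeros);
  dW.zeros(Cin, 4 * Cout);
  db.zeros(Cout);
  arma::fmat dYt(hw * B, Cout);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    for (int bb = 0; bb < B; ++bb)
      for (int c = 0; c < Cout; ++c) {
        float* dst = dYt.colptr(c) + hw * bb;
        const arma::uword sl = c + (arma::uword)Cout * bb;
        for (int j = 0; j < Wi; ++j)
          for (int i = 0; i < Hi; ++i)
            dst[i + (arma::uword)Hi * j] = dy(2 * i + di, 2 * j + dj, sl);
      }
    dX += dYt * cw.W.cols(t * Cout, (t + 1) * Cout - 1).t();
    dW.cols(t * Cout, (t + 1) * Cout - 1) = X.t() * dYt;
    db += arma::sum(dYt, 0).t();
  }
  arma::fcube dxc(Hi, Wi, (arma::uword)Cin * B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cin; ++c)
      std::copy(dX.colptr(c) + hw * bb, dX.colptr(c) + hw * (bb + 1),
                dxc.slice_memptr(c + (arma::uword)Cin * bb));
  return dxc;
}

static arma::fcube cat_ch_f(const arma::fcube& a, int Ca, const arma::fcube& b,
                            int Cb, int B) {
  const arma::uword hw = (arma::uword)a.n_rows * a.n_cols;
  arma::fcube out(a.n_rows, a.n_cols, (arma::uword)(Ca + Cb) * B);
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < Ca; ++c)
      std::copy(a.slice_memptr(c + (arma::uword)Ca * bb),
                a.slice_memptr(c + (arma::uword)Ca * bb) + hw,
                out.slice_memptr(c + (arma::uword)(Ca + Cb) * bb));
    for (int c = 0; c < Cb; ++c)
      std::copy(b.slice_memptr(c + (arma::uword)Cb * bb),
                b.slice_memptr(c + (arma::uword)Cb * bb) + hw,
                out.slice_memptr(Ca + c + (arma::uword)(Ca + Cb) * bb));
  }
  return out;
}

struct UNetPars {
  ConvPar e_c1[5], e_c2[5], d_up[4], d_c1[4], d_c2[4], out;
};

static UNetPars load_unet(const List& params) {
  UNetPars u;
  char nm[16];
  for (int i = 0; i < 5; ++i) {
    snprintf(nm, sizeof(nm), "e%d.c1", i + 1); u.e_c1[i] = get_par(params, nm);
    snprintf(nm, sizeof(nm), "e%d.c2", i + 1); u.e_c2[i] = get_par(params, nm);
  }
  for (int i = 0; i < 4; ++i) {
    snprintf(nm, sizeof(nm), "d%d.up", i + 1); u.d_up[i] = get_par(params, nm);
    snprintf(nm, sizeof(nm), "d%d.c1", i + 1); u.d_c1[i] = get_par(params, nm);
    snprintf(nm, sizeof(nm), "d%d.c2", i + 1); u.d_c2[i] = get_par(params, nm);
  }
  u.out = get_par(params, "out");
  return u;
}

struct UNetCache {
  arma::fcube e_in[5], e_h1[5], enc[5];
  std::vector<int> poolidx[4];
  arma::fcube d_in[4], d_u[4], d_cat[4], d_h1[4], d_h2[4];
  arma::fcube top, z;
  arma::fmat e_c1_cols[5], e_c2_cols[5], d_c1_cols[4], d_c2_cols[4],
    out_cols;
  bool keep_cols = false;
  int ch[5], B;
};

static void unet_fwd_native(const UNetPars& u, const arma::fcube& x, int B,
                            UNetCache& cc) {
  for (int i = 0; i < 5; ++i) cc.ch[i] = u.e_c1[i].W.n_cols;
  cc.B = B;
  arma::fcube a = x;
  int C = 1;
  arma::fmat* keep;
  for (int i = 0; i < 5; ++i) {
    cc.e_in[i] = a;
    keep = cc.keep_cols ? &cc.e_c1_cols[i] : nullptr;
    arma::fcube h1 = conv_f(cc.e_in[i], C, B, u.e_c1[i], 3, 1, 1, keep);
    relu_(h1);
    cc.e_h1[i] = h1;
    keep = cc.keep_cols ? &cc.e_c2_cols[i] : nullptr;
    arma::fcube h2 = conv_f(h1, cc.ch[i], B, u.e_c2[i], 3, 1, 1, keep);
    relu_(h2);
    cc.enc[i] = h2;
    C = cc.ch[i];
    if (i < 4) a = maxpool_f(cc.enc[i], cc.poolidx[i]);
  }
  arma::fcube d = cc.enc[4];
  int Cd = cc.ch[4];
  for (int i = 3; i >= 0; --i) {
    cc.d_in[i] = d;
    arma::fcube uu = upconv_f(d, Cd, B, u.d_up[i]);
    relu_(uu);
    cc.d_u[i] = uu;
    cc.d_cat[i] = cat_ch_f(cc.enc[i], cc.ch[i], cc.d_u[i], cc.ch[i], B);
    keep = cc.keep_cols ? &cc.d_c1_cols[i] : nullptr;
    arma::fcube h1 = conv_f(cc.d_cat[i], 2 * cc.ch[i], B, u.d_c1[i], 3, 1, 1,
                            keep);
    relu_(h1);
    cc.d_h1[i] = h1;
    keep = cc.keep_cols ? &cc.d_c2_cols[i] : nullptr;
    arma::fcube h2 = conv_f(h1, cc.ch[i], B, u.d_c2[i], 3, 1, 1, keep);
    relu_(h2);
    cc.d_h2[i] = h2;
    d = cc.d_h2[i];
    Cd = cc.ch[i];
  }
  cc.top = d;
  keep = cc.keep_cols ? &cc.out_cols : nullptr;
  cc.z = conv_f(cc.top, cc.ch[0], B, u.out, 1, 1, 0, keep);
}

// [[Rcpp::export]]
NumericVector cnu_predict(List params, NumericVector x) {
  int C, B;
  arma::fcube xc = as_fcube4(x, C, B);
  UNetPars u = load_unet(params);
  UNetCache cc;
  unet_fwd_native(u, xc, B, cc);
  arma::fcube p = cc.z;
  float* q = p.memptr();
  for (arma::uword i = 0; i < p.n_elem; ++i)
    q[i] = 1.0f / (1.0f + std::exp(-q[i]));
  return as_rarray4(p, 1, B);
}

// Forward + focal loss + backward; returns loss and named gradient list.
// [[Rcpp::export]]
List cnu_step(List params, NumericVector x, NumericVector y, double gamma,
              double alpha) {
  int C, B, Cy, By;
  arma::fcube xc = as_fcube4(x, C, B);
  arma::fcube yc = as_fcube4(y, Cy, By);
  UNetPars u = load_unet(params);
  UNetCache cc;
  cc.keep_cols = true;
  unet_fwd_native(u, xc, B, cc);

  // focal loss + d/dz, averaged over all pixels of the batch
  const double eps = 1e-7;
  const arma::uword N = cc.z.n_elem;
  double loss = 0.0;
  arma::fcube dz(cc.z.n_rows, cc.z.n_cols, cc.z.n_slices);
  const float* zp = cc.z.memptr();
  const float* yp = yc.memptr();
  float* dp = dz.memptr();
  for (arma::uword i = 0; i < N; ++i) {
    double p = 1.0 / (1.0 + std::exp(-(double)zp[i]));
    p = std::min(std::max(p, eps), 1.0 - eps);
    double dldp;
    if (yp[i] >= 0.5f) {
      loss += alpha * std::pow(1 - p, gamma) * (-std::log(p));
      dldp = alpha * (gamma * std::pow(1 - p, gamma - 1) * std::log(p) -
                      std::pow(1 - p, gamma) / p);
    } else {
      loss += (1 - alpha) * std::pow(p, gamma) * (-std::log(1 - p));
      dldp = (1 - alpha) * (gamma * std::pow(p, gamma - 1) *
                              (-std::log(1 - p)) +
                            std::pow(p, gamma) / (1 - p));
    }
    dp[i] = (float)(dldp * p * (1 - p) / (double)N);
  }
  loss /= (double)N;

  List g;
  arma::fmat dW; arma::fvec db;
  arma::fcube dd = conv_b(cc.top, cc.ch[0], B, u.out, dz, 1, 1, 0, dW, db,
                          &cc.out_cols);
  g["out.W"] = as_rmat(dW);
  g["out.b"] = NumericVector(db.begin(), db.end());
  arma::fcube denc[5];
  char nm[16];
  for (int i = 0; i < 4; ++i) {
    relu_gate(dd, cc.d_h2[i]);
    arma::fcube dh1 = conv_b(cc.d_h1[i], cc.ch[i], B, u.d_c2[i], dd, 3, 1, 1,
                             dW, db, &cc.d_c2_cols[i]);
    snprintf(nm, sizeof(nm), "d%d.c2.W", i + 1); g[nm] = as_rmat(dW);
    snprintf(nm, sizeof(nm), "d%d.c2.b", i + 1);
    g[nm] = NumericVector(db.begin(), db.end());
    relu_gate(dh1, cc.d_h1[i]);
    arma::fcube dcat = conv_b(cc.d_cat[i], 2 * cc.ch[i], B, u.d_c1[i], dh1,
                              3, 1, 1, dW, db, &cc.d_c1_cols[i]);
    snprintf(nm, sizeof(nm), "d%d.c1.W", i + 1); g[nm] = as_rmat(dW);
    snprintf(nm, sizeof(nm), "d%d.c1.b", i + 1);
    g[nm] = NumericVector(db.begin(), db.end());
    // split concat: first ch[i] channels to the skip, rest to the up path
    const arma::uword hw = (arma::uword)dcat.n_rows * dcat.n_cols;
    arma::fcube dskip(dcat.n_rows, dcat.n_cols, (arma::uword)cc.ch[i] * B);
    arma::fcube du(dcat.n_rows, dcat.n_cols, (arma::uword)cc.ch[i] * B);
    for (int bb = 0; bb < B; ++bb)
      for (int c = 0; c < cc.ch[i]; ++c) {
        std::copy(dcat.slice_memptr(c + (arma::uword)2 * cc.ch[i] * bb),
                  dcat.slice_memptr(c + (arma::uword)2 * cc.ch[i] * bb) + hw,
                  dskip.slice_memptr(c + (arma::uword)cc.ch[i] * bb));
        std::copy(
          dcat.slice_memptr(cc.ch[i] + c + (arma::uword)2 * cc.ch[i] * bb),
          dcat.slice_memptr(cc.ch[i] + c + (arma::uword)2 * cc.ch[i] * bb) +
            hw,
          du.slice_memptr(c + (arma::uword)cc.ch[i] * bb));
      }
    denc[i] = dskip;
    relu_gate(du, cc.d_u[i]);
    const int Cd = (i == 3) ? cc.ch[4] : cc.ch[i + 1];
    arma::fcube ddn = upconv_b(cc.d_in[i], Cd, B, u.d_up[i], du, dW, db);
    snprintf(nm, sizeof(nm), "d%d.up.W", i + 1); g[nm] = as_rmat(dW);
    snprintf(nm, sizeof(nm), "d%d.up.b", i + 1);
    g[nm] = NumericVector(db.begin(), db.end());
    dd = ddn;
  }
  denc[4] = dd;
  for (int i = 4; i >= 0; --i) {
    arma::fcube da2 = denc[i];
    relu_gate(da2, cc.enc[i]);
    arma::fcube dh1 = conv_b(cc.e_h1[i], cc.ch[i], B, u.e_c2[i], da2, 3, 1, 1,
                             dW, db, &cc.e_c2_cols[i]);
    snprintf(nm, sizeof(nm), "e%d.c2.W", i + 1); g[nm] = as_rmat(dW);
    snprintf(nm, sizeof(nm), "e%d.c2.b", i + 1);
    g[nm] = NumericVector(db.begin(), db.end());
    relu_gate(dh1, cc.e_h1[i]);
    const int Cin = (i == 0) ? 1 : cc.ch[i - 1];
    arma::fcube din = conv_b(cc.e_in[i], Cin, B, u.e_c1[i], dh1, 3, 1, 1, dW,
                             db, &cc.e_c1_cols[i]);
    snprintf(nm, sizeof(nm), "e%d.c1.W", i + 1); g[nm] = as_rmat(dW);
    snprintf(nm, sizeof(nm), "e%d.c1.b", i + 1);
    g[nm] = NumericVector(db.begin(), db.end());
    if (i > 0)
      denc[i - 1] += maxpool_b(cc.poolidx[i - 1], din, cc.enc[i - 1].n_rows,
                               cc.enc[i - 1].n_cols,
                               (int)cc.enc[i - 1].n_slices);
  }
  return List::create(_["loss"] = loss, _["grads"] = g);
}
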