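// Stride-1 'same' 2-D convolution kernels and fused instance-norm helpers
// for the GAN core.
// Feature maps are R arrays with dim c(H, W, N, C) (column-major, row
// fastest); conv weights are matrices of dim (C_in * k * k) x C_out with
// column index kh + k*kw + k*k*c_in (0-based). Only odd k with
// pad = (k-1)/2 is used. The im2col/col2im paths copy contiguous
// h-runs, so the dominant cost is the GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_fill(const double* x, arma::mat& col,
                        int H, int W, int N, int C, int k, int pad) {
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* dst = col.colptr(kh + k * kw + k * k * c);
        int h0 = std::max(0, pad - kh);            // valid output rows
        int h1 = std::min(H, H + pad - kh);        // exclusive
        for (int n = 0; n < N; ++n) {
          const double* xn = x + (size_t)H * W * (n + (size_t)N * c);
          for (int w = 0; w < W; ++w) {
            int ws = w + kw - pad;
            double* d = dst + H * (w + (size_t)W * n);
            if (ws < 0 || ws >= W) { std::fill(d, d + H, 0.0); continue; }
            const double* src = xn + (size_t)H * ws + (kh - pad);
            if (h0 > 0) std::fill(d, d + h0, 0.0);
            if (h1 > h0) std::copy(src + h0, src + h1, d + h0);
            if (h1 < H) std::fill(d + h1, d + H, 0.0);
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& col, double* dx,
                       int H, int W, int N, int C, int k, int pad) {
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* src0 = col.colptr(kh + k * kw + k * k * c);
        int h0 = std::max(0, pad - kh);
        int h1 = std::min(H, H + pad - kh);
        for (int n = 0; n < N; ++n) {
          double* xn = dx + (size_t)H * W * (n + (size_t)N * c);
          for (int w = 0; w < W; ++w) {
            int ws = w + kw - pad;
            if (ws < 0 || ws >= W) continue;
            const double* s = src0 + H * (w + (size_t)W * n);
            double* d = xn + (size_t)H * ws + (kh - pad);
            for (int h = h0; h < h1; ++h) d[h] += s[h];
          }
        }
      }
    }
  }
}

// single-precision twin of im2col_fill for the large-tensor fast path
static void im2col_fill_f(const double* x, arma::fmat& col,
                          int H, int W, int N, int C, int k, int pad) {
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        float* dst = col.colptr(kh + k * kw + k * k * c);
        int h0 = std::max(0, pad - kh);
        int h1 = std::min(H, H + pad - kh);
        for (int n = 0; n < N; ++n) {
          const double* xn = x + (size_t)H * W * (n + (size_t)N * c);
          for (int w = 0; w < W; ++w) {
            int ws = w + kw - pad;
            float* d = dst + H * (w + (size_t)W * n);
            if (ws < 0 || ws >= W) { std::fill(d, d + H, 0.0f); continue; }
            const double* src = xn + (size_t)H * ws + (kh - pad);
            if (h0 > 0) std::fill(d, d + h0, 0.0f);
            for (int h = h0; h < h1; ++h) d[h] = (float)src[h];
            if (h1 < H) std::fill(d + h1, d + H, 0.0f);
          }
        }
      }
    }
  }
}

// large convolutions run their GEMMs in single precision: memory-bandwidth
// and GEMM cost halve, and the ~1e-7 relative rounding is far below the
// optimisation noise of SGD
static const size_t kFloatPathFlop = (size_t)1 << 22;

static bool use_float_path(size_t R, size_t K, size_t Co) {
  return R * K * Co > kFloatPathFlop;
}

// [[Rcpp::export(name = ".nn_conv_fw")]]
NumericVector nn_conv_fw(NumericVector x, NumericMatrix wmat, NumericVector b) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], N = dm[2], C = dm[3];
  int k = (int)std::lround(std::sqrt((double)wmat.nrow() / C));
  if (k * k * C != wmat.nrow()) stop("weight rows inconsistent with input channels");
  int pad = (k - 1) / 2, Co = wmat.ncol();
  const int R = H * W * N;
  NumericVector out((size_t)R * Co);
  if (use_float_path(R, wmat.nrow(), Co)) {
    arma::fmat col(R, C * k * k);
    im2col_fill_f(x.begin(), col, H, W, N, C, k, pad);
    arma::fmat wm = arma::conv_to<arma::fmat>::from(
      arma::mat(wmat.begin(), wmat.nrow(), Co, false));
    arma::fmat y = col * wm;
    double* o = out.begin();
    for (int j = 0; j < Co; ++j) {
      const float* yj = y.colptr(j);
      double bj = b[j];
      for (int i = 0; i < R; ++i) o[(size_t)R * j + i] = yj[i] + bj;
    }
  } else {
    arma::mat col(R, C * k * k);
    im2col_fill(x.begin(), col, H, W, N, C, k, pad);
    arma::mat wm(wmat.begin(), wmat.nrow(), Co, false);
    arma::mat y = col * wm;
    y.each_row() += arma::rowvec(b.begin(), Co);
    std::copy(y.begin(), y.end(), out.begin());
  }
  out.attr("dim") = IntegerVector::create(H, W, N, Co);
  return out;
}

// [[Rcpp::export(name = ".nn_conv_bw")]]
List nn_conv_bw(NumericVector x, NumericMatrix wmat, NumericVector dy,
                bool want_dx, bool want_dw) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], N = dm[2], C = dm[3];
  int k = (int)std::lround(std::sqrt((double)wmat.nrow() / C));
  int pad = (k - 1) / 2, Co = wmat.ncol();
  const int R = H * W * N;
  arma::mat dym(dy.begin(), R, Co, false);
  arma::mat wm(wmat.begin(), wmat.nrow(), Co, false);

  NumericVector db(Co);
  arma::rowvec dbv = arma::sum(dym, 0);
  std::copy(dbv.begin(), dbv.end(), db.begin());

  List res = List::create(Named("dx") = R_NilValue,
                          Named("dw") = R_NilValue,
                          Named("db") = db);
  if (use_float_path(R, wmat.nrow(), std::max(Co, C))) {
    arma::fmat dymf = arma::conv_to<arma::fmat>::from(dym);
    if (want_dw) {
      arma::fmat col(R, C * k * k);
      im2col_fill_f(x.begin(), col, H, W, N, C, k, pad);
      arma::fmat dw = col.t() * dymf;
      NumericMatrix dwR(dw.n_rows, dw.n_cols);
      std::copy(dw.begin(), dw.end(), dwR.begin());
      res["dw"] = dwR;
    }
    if (want_dx) {
      arma::fmat wmf = arma::conv_to<arma::fmat>::from(wm);
      arma::fmat dcolf = dymf * wmf.t();
      arma::mat dcol = arma::conv_to<arma::mat>::from(dcolf);
      NumericVector dx((size_t)R * C);
      std::fill(dx.begin(), dx.end(), 0.0);
      col2im_acc(dcol, dx.begin(), H, W, N, C, k, pad);
      dx.attr("dim") = IntegerVector::create(H, W, N, C);
      res["dx"] = dx;
    }
    return res;
  }
  if (want_dw) {
    arma::mat col(R, C * k * k);
    im2col_fill(x.begin(), col, H, W, N, C, k, pad);
    arma::mat dw = col.t() * dym;
    NumericMatrix dwR(dw.n_rows, dw.n_cols);
    std::copy(dw.begin(), dw.end(), dwR.begin());
    res["dw"] = dwR;
  }
  if (want_dx) {
    arma::mat dcol = dym * wm.t();
    NumericVector dx((size_t)R * C);
    std::fill(dx.begin(), dx.end(), 0.0);
    col2im_acc(dcol, dx.begin(), H, W, N, C, k, pad);
    dx.attr("dim") = IntegerVector::create(H, W, N, C);
    res["dx"] = dx;
  }
  return res;
}

// Fused instance-norm forward over an (hw x nc) matrix: per-column
// normalisation with affine gain/bias vectors gf, bf (length nc).
// [[Rcpp::export(name = ".nn_in_fw")]]
List nn_in_fw(NumericMatrix x, NumericVector gf, NumericVector bf,
              double eps) {
  int hw = x.nrow(), nc = x.ncol();
  NumericMatrix y(hw, nc), xhat(hw, nc);
  NumericVector inv(nc);
  for (int j = 0; j < nc; ++j) {
    const double* xc = &x(0, j);
    double mu = 0; for (int i = 0; i < hw; ++i) mu += xc[i];
    mu /= hw;
    double v = 0; for (int i = 0; i < hw; ++i) {
      double d = xc[i] - mu; v += d * d;
    }
    v /= hw;
    double iv = 1.0 / std::sqrt(v + eps);
    inv[j] = iv;
    double g = gf[j], b = bf[j];
    double* yj = &y(0, j); double* hj = &xhat(0, j);
    for (int i = 0; i < hw; ++i) {
      double h = (xc[i] - mu) * iv;
      hj[i] = h;
      yj[i] = g * h + b;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("inv") = inv);
}

// Fused instance-norm backward: returns dx and per-column dgamma, dbeta.
// [[Rcpp::export(name = ".nn_in_bw")]]
List nn_in_bw(NumericMatrix dy, NumericMatrix xhat, NumericVector inv,
              NumericVector gf) {
  int hw = dy.nrow(), nc = dy.ncol();
  NumericMatrix dx(hw, nc);
  NumericVector dgam(nc), dbet(nc);
  for (int j = 0; j < nc; ++j) {
    const double* dyj = &dy(0, j);
    const double* hj = &xhat(0, j);
    double sg = 0, sb = 0, sh = 0;
    for (int i = 0; i < hw; ++i) {
      sg += dyj[i] * hj[i];
      sb += dyj[i];
    }
    dgam[j] = sg; dbet[j] = sb;
    double g = gf[j];
    double m1 = g * sb / hw;          // mean of dxhat
    double m2 = g * sg / hw;          // mean of dxhat * xhat
    sh = inv[j];
    double* dxj = &dx(0, j);
    for (int i = 0; i < hw; ++i)
      dxj[i] = sh * (g * dyj[i] - m1 - hj[i] * m2);
  }
  return List::create(Named("dx") = dx, Named("dgam") = dgam,
                      Named("dbet") = dbet);
}

// 2x2 average pooling over (H, W, N, C) arrays.
// [[Rcpp::export(name = ".nn_pool2_fw")]]
NumericVector nn_pool2_fw(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], NC = dm[2] * dm[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * NC);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int s = 0; s < NC; ++s) {
    const double* xs = xp + (size_t)H * W * s;
    double* ys = yp + (size_t)Ho * Wo * s;
    for (int w = 0; w < Wo; ++w) {
      const double* c0 = xs + (size_t)H * (2 * w);
      const double* c1 = xs + (size_t)H * (2 * w + 1);
      double* yc = ys + (size_t)Ho * w;
      for (int h = 0; h < Ho; ++h)
        yc[h] = 0.25 * (c0[2*h] + c0[2*h+1] + c1[2*h] + c1[2*h+1]);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, dm[2], dm[3]);
  return y;
}

// [[Rcpp::export(name = ".nn_pool2_bw")]]
NumericVector nn_pool2_bw(NumericVector dy) {
  IntegerVector dm = dy.attr("dim");
  int Ho = dm[0], Wo = dm[1], NC = dm[2] * dm[3];
  int H = Ho * 2, W = Wo * 2;
  NumericVector dx((size_t)H * W * NC);
  const double* dp = dy.begin(); double* xp = dx.begin();
  for (int s = 0; s < NC; ++s) {
    const double* ds = dp + (size_t)Ho * Wo * s;
    double* xs = xp + (size_t)H * W * s;
    for (int w = 0; w < Wo; ++w) {
      const double* dc = ds + (size_t)Ho * w;
      double* c0 = xs + (size_t)H * (2 * w);
      double* c1 = xs + (size_t)H * (2 * w + 1);
      for (int h = 0; h < Ho; ++h) {
        double q = 0.25 * dc[h];
        c0[2*h] = q; c0[2*h+1] = q; c1[2*h] = q; c1[2*h+1] = q;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, dm[2], dm[3]);
  return dx;
}

// 2x nearest-neighbour upsampling.
// [[Rcpp::export(name = ".nn_up2_fw")]]
NumericVector nn_up2_fw(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], NC = dm[2] * dm[3];
  int Ho = H * 2, Wo = W * 2;
  NumericVector y((size_t)Ho * Wo * NC);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int s = 0; s < NC; ++s) {
    const double* xs = xp + (size_t)H * W * s;
    double* ys = yp + (size_t)Ho * Wo * s;
    for (int w = 0; w < W; ++w) {
      const double* xc = xs + (size_t)H * w;
      double* y0 = ys + (size_t)Ho * (2 * w);
      double* y1 = ys + (size_t)Ho * (2 * w + 1);
      for (int h = 0; h < H; ++h) {
        double v = xc[h];
        y0[2*h] = v; y0[2*h+1] = v; y1[2*h] = v; y1[2*h+1] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, dm[2], dm[3]);
  return y;
}

// [[Rcpp::export(name = ".nn_up2_bw")]]
NumericVector nn_up2_bw(NumericVector dy) {
  IntegerVector dm = dy.attr("dim");
  int Ho = dm[0], Wo = dm[1], NC = dm[2] * dm[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * NC);
  const double* dp = dy.begin(); double* xp = dx.begin();
  for (int s = 0; s < NC; ++s) {
    const double* ds = dp + (size_t)Ho * Wo * s;
    double* xs = xp + (size_t)H * W * s;
    for (int w = 0; w < W; ++w) {
      const double* d0 = ds + (size_t)Ho * (2 * w);
      const double* d1 = ds + (size_t)Ho * (2 * w + 1);
      double* xc = xs + (size_t)H * w;
      for (int h = 0; h < H; ++h)
        xc[h] = d0[2*h] + d0[2*h+1] + d1[2*h] + d1[2*h+1];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, dm[2], dm[3]);
  return dx;
}

// Separable 3x3 binomial smoothing ([1,2,1]/4 per axis, zero-pad with
// edge renormalisation y = (B0 x) / c where c = B0 1). Used as a fixed
// antialiasing filter after the generator's final nearest-neighbour
// upsampling; the adjoint pass is B0 (dy / c).
static void blur1d_cols(const double* x, double* y, int H, int W) {
  for (int w = 0; w < W; ++w) {
    const double* xc = x + (size_t)H * w;
    double* yc = y + (size_t)H * w;
    if (H == 1) { yc[0] = xc[0] * 0.5; continue; }
    yc[0] = 0.5 * xc[0] + 0.25 * xc[1];
    for (int h = 1; h < H - 1; ++h)
      yc[h] = 0.25 * xc[h-1] + 0.5 * xc[h] + 0.25 * xc[h+1];
    yc[H-1] = 0.25 * xc[H-2] + 0.5 * xc[H-1];
  }
}

static void blur_panel(const double* x, double* y, double* tmp,
                       int H, int W) {
  blur1d_cols(x, tmp, H, W);
  for (int w = 0; w < W; ++w) {
    const double* tm = tmp + (size_t)H * w;
    const double* tl = (w > 0) ? tmp + (size_t)H * (w - 1) : nullptr;
    const double* tr = (w < W - 1) ? tmp + (size_t)H * (w + 1) : nullptr;
    double* yc = y + (size_t)H * w;
    for (int h = 0; h < H; ++h) {
      double v = 0.5 * tm[h];
      if (tl) v += 0.25 * tl[h];
      if (tr) v += 0.25 * tr[h];
      yc[h] = v;
    }
  }
}

static double edge_c(int i, int n) {
  return (n > 1 && (i == 0 || i == n - 1)) ? 0.75 : 1.0;
}

// [[Rcpp::export(name = ".nn_blur3")]]
NumericVector nn_blur3(NumericVector x, bool adjoint) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], NC = dm[2] * dm[3];
  NumericVector y((size_t)H * W * NC);
  std::vector<double> tmp((size_t)H * W), xin((size_t)H * W);
  for (int s = 0; s < NC; ++s) {
    const double* xs = x.begin() + (size_t)H * W * s;
    double* ys = y.begin() + (size_t)H * W * s;
    if (!adjoint) {
      blur_panel(xs, ys, tmp.data(), H, W);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          ys[h + (size_t)H * w] /= edge_c(h, H) * edge_c(w, W);
    } else {
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          xin[h + (size_t)H * w] = xs[h + (size_t)H * w] /
            (edge_c(h, H) * edge_c(w, W));
      blur_panel(xin.data(), ys, tmp.data(), H, W);
    }
  }
  y.attr("dim") = dm;
  return y;
}

// ReLU forward / backward.
// [[Rcpp::export(name = ".nn_relu_fw")]]
NumericVector nn_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".nn_relu_bw")]]
NumericVector nn_relu_bw(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
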