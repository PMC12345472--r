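// Hot loops for 2-D convolution and max pooling.
// Tensor layout everywhere: R array dim c(H, W, C, N), column-major, so a
// single sample's data are contiguous. Convolution weights: c(KH, KW, C, OC).
// im2col row index = kh + KH*(kw + KW*c), matching the column-major
// flattening of the first three weight dimensions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col_one(const double* x, int H, int W, int C,
                       int KH, int KW, int stride, int pad,
                       arma::mat& cols) {
  const int OH = out_size(H, KH, stride, pad);
  const int OW = out_size(W, KW, stride, pad);
  // cols: (KH*KW*C) x (OH*OW); spatial position index = oh + OH*ow
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int col = oh + OH * ow;
      double* dst = cols.colptr(col);
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < KW; ++kw) {
          const int w = w0 + kw;
          const bool wok = (w >= 0 && w < W);
          for (int kh = 0; kh < KH; ++kh) {
            const int h = h0 + kh;
            const int row = kh + KH * (kw + KW * c);
            dst[row] = (wok && h >= 0 && h < H) ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int KH, int KW, int stride, int pad, double* dx) {
  const int OH = out_size(H, KH, stride, pad);
  const int OW = out_size(W, KW, stride, pad);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int col = oh + OH * ow;
      const double* src = cols.colptr(col);
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int kw = 0; kw < KW; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += src[kh + KH * (kw + KW * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], OC = wd[3];
  if (wd[2] != C) stop("conv2d: channel mismatch");
  const int OH = out_size(H, KH, stride, pad);
  const int OW = out_size(W, KW, stride, pad);
  if (OH < 1 || OW < 1) stop("conv2d: input smaller than kernel");

  arma::mat wm(const_cast<double*>(w.begin()), KH * KW * C, OC, false, true);
  NumericVector y((size_t)OH * OW * OC * N);
  y.attr("dim") = IntegerVector::create(OH, OW, OC, N);

  arma::mat cols(KH * KW * C, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pad, cols);
    // y_n (OH*OW x OC) = cols' * wm ; stored column-major = [OH,OW,OC]
    arma::mat yn(y.begin() + (size_t)OH * OW * OC * n, OH * OW, OC, false, true);
    yn = cols.t() * wm;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], OC = wd[3];
  const int OH = out_size(H, KH, stride, pad);
  const int OW = out_size(W, KW, stride, pad);

  arma::mat wm(const_cast<double*>(w.begin()), KH * KW * C, OC, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)KH * KW * C * OC);
  dw.attr("dim") = wd;
  arma::mat dwm(dw.begin(), KH * KW * C, OC, false, true);

  arma::mat cols(KH * KW * C, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pad, cols);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)OH * OW * OC * n,
                  OH * OW, OC, false, true);
    dwm += cols * dyn;                       // (KKC x OHOW)(OHOW x OC)
    arma::mat dcols = wm * dyn.t();          // (KKC x OC)(OC x OHOW)
    col2im_one(dcols, H, W, C, KH, KW, stride, pad,
               dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  if (OH < 1 || OW < 1) stop("maxpool: input smaller than kernel");

  NumericVector y((size_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  IntegerVector arg((size_t)OH * OW * C * N); // 0-based flat index into x

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const size_t base_n = (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      const size_t base_c = base_n + (size_t)H * W * c;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          const int h0 = oh * stride - pad, w0 = ow * stride - pad;
          double best = -std::numeric_limits<double>::infinity();
          int bidx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              const double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; bidx = h + H * w; }
            }
          }
          // pooled index stored as [OH,OW,C,N] column-major
          const size_t oidx = (size_t)oh + OH * ((size_t)ow + (size_t)OW * (c + (size_t)C * n));
          y[oidx] = (bidx >= 0) ? best : 0.0;
          arg[oidx] = (bidx >= 0) ? (int)(base_c + bidx) : -1;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector arg, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (arg[i] >= 0) dx[arg[i]] += dy[i];
  }
  return dx;
}

// ---- fused batch-norm and relu kernels --------------------------------
// Per-channel BN over an (H,W,C,N) array; x is treated as (hw, C, N).

// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x, int hw, int C, int N) {
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + (size_t)hw * (c + (size_t)C * n);
      for (int i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / ((double)hw * N);
    mu[c] = m;
    double v = s2 / ((double)hw * N) - m * m;
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_apply")]]
NumericVector bn_apply(NumericVector x, NumericVector scale,
                       NumericVector shift, int hw, int C, int N) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double sc = scale[c], sh = shift[c];
      const double* p = x.begin() + (size_t)hw * (c + (size_t)C * n);
      double* q = y.begin() + (size_t)hw * (c + (size_t)C * n);
      for (int i = 0; i < hw; ++i) q[i] = p[i] * sc + sh;
    }
  }
  return y;
}

// dy, x -> dx plus per-channel dgamma/dbeta, using cached mu/invstd/gamma
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector dy, NumericVector x, NumericVector mu,
            NumericVector invstd, NumericVector gamma,
            int hw, int C, int N) {
  const double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C), sum_dxhat(C), sum_dxhat_xhat(C);
  for (int c = 0; c < C; ++c) {
    double sd = 0, sdx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)hw * (c + (size_t)C * n);
      const double* pd = dy.begin() + off;
      const double* px = x.begin() + off;
      for (int i = 0; i < hw; ++i) {
        const double xhat = (px[i] - mu[c]) * invstd[c];
        sd += pd[i];
        sdx += pd[i] * xhat;
      }
    }
    dbeta[c] = sd;
    dgamma[c] = sdx;
    sum_dxhat[c] = sd * gamma[c];
    sum_dxhat_xhat[c] = sdx * gamma[c];
  }
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], is = invstd[c];
    const double mdx = sum_dxhat[c] / m, mdxx = sum_dxhat_xhat[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)hw * (c + (size_t)C * n);
      const double* pd = dy.begin() + off;
      const double* px = x.begin() + off;
      double* q = dx.begin() + off;
      for (int i = 0; i < hw; ++i) {
        const double xhat = (px[i] - mu[c]) * is;
        q[i] = (pd[i] * g - mdx - xhat * mdxx) * is;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  return dx;
}

// y = a + b elementwise (avoids an extra R allocation in residual adds)
// [[Rcpp::export(name = ".axpy")]]
NumericVector add_into(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = a[i] + b[i];
  return y;
}
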