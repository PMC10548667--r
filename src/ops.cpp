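// Low-level tensor kernels for the detector.
//
// Layout conventions (match the R side, column-major):
//   activations: array dim (H, W, C, N)   -> x[h + H*(w + W*(c + C*n))]
//   conv weight: array dim (k, k, Cin, Cout)
// Convolution is cross-correlation with symmetric zero padding; GEMM via
// im2col so BLAS does the work.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// exp via range reduction (x = n*ln2 + r) and a degree-6 Taylor polynomial
// on |r| <= ln2/2; relative error ~1e-7, several times faster than libm.
// Used only inside the elementwise activation kernels.
static inline double fast_exp(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) return INFINITY;
  double t = x * 1.4426950408889634;  // x / ln2
  int n = (int)(t >= 0 ? t + 0.5 : t - 0.5);
  double r = x - n * 0.6931471805599453;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720))))));
  union { uint64_t i; double d; } u;   // 2^n without libm
  u.i = (uint64_t)(n + 1023) << 52;
  return p * u.d;
}

static inline double fast_sigmoid(double x) {
  return 1.0 / (1.0 + fast_exp(-x));
}

// Fill the im2col matrix for one sample: M is (Ho*Wo) x (k*k*Cin),
// column r = dh + k*(dw + k*ci), row = oh + Ho*ow.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& M) {
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* col = M.colptr((size_t)dh + k * ((size_t)dw + k * ci));
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride - pad + dw;
          double* dst = col + (size_t)Ho * ow;
          if (w < 0 || w >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * w;
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride - pad + dh;
            dst[oh] = (h < 0 || h >= H) ? 0.0 : src[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  bool pointwise = (k == 1 && stride == 1 && pad == 0);
  arma::mat M;
  if (!pointwise) M.set_size((size_t)Ho * Wo, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat O(out.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    if (pointwise) {
      // 1x1 stride-1: the sample slice is already the im2col matrix
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                  (size_t)H * W, C, false, true);
      O = X * Wm;
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, M);
      O = M * Wm;
    }
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad, bool need_gx, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  NumericVector gw(Rf_allocVector(REALSXP, (R_xlen_t)k * k * C * Cout));
  gw.attr("dim") = wd;
  arma::mat GW(gw.begin(), (size_t)k * k * C, Cout, false, true);
  GW.zeros();

  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(Rf_allocVector(REALSXP, x.size()));
    std::fill(gx.begin(), gx.end(), 0.0);
    gx.attr("dim") = xd;
  }
  NumericVector gb(Cout);

  bool pointwise = (k == 1 && stride == 1 && pad == 0);
  arma::mat M;
  if (!pointwise) M.set_size((size_t)Ho * Wo, (size_t)k * k * C);
  arma::mat Gcol;
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    if (pointwise) {
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                  (size_t)H * W, C, false, true);
      GW += X.t() * G;
      if (has_bias)
        for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(G.col(co));
      if (need_gx) {
        arma::mat GX(gx.begin() + (size_t)H * W * C * n, (size_t)H * W, C, false, true);
        GX = G * Wm.t();
      }
      continue;
    }
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, M);
    GW += M.t() * G;
    if (has_bias)
      for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(G.col(co));
    if (need_gx) {
      Gcol = G * Wm.t();  // (Ho*Wo) x (k*k*C)
      double* gxs = gx.begin() + (size_t)H * W * C * n;
      for (int ci = 0; ci < C; ++ci) {
        double* gxc = gxs + (size_t)H * W * ci;
        for (int dw = 0; dw < k; ++dw) {
          for (int dh = 0; dh < k; ++dh) {
            const double* col = Gcol.colptr((size_t)dh + k * ((size_t)dw + k * ci));
            for (int ow = 0; ow < Wo; ++ow) {
              int wpos = ow * stride - pad + dw;
              if (wpos < 0 || wpos >= W) continue;
              const double* src = col + (size_t)Ho * ow;
              double* dst = gxc + (size_t)H * wpos;
              for (int oh = 0; oh < Ho; ++oh) {
                int hpos = oh * stride - pad + dh;
                if (hpos >= 0 && hpos < H) dst[hpos] += src[oh];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw, _["gb"] = gb);
}

// Stride-1 max pooling with (k-1)/2 padding; records per-output argmax as a
// 0-based linear index into the sample slice so backward is a scatter-add.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = (k - 1) / 2;
  if (k > H + 2 * pad || k > W + 2 * pad) stop("maxpool: kernel larger than input");
  NumericVector out(Rf_allocVector(REALSXP, x.size()));
  out.attr("dim") = xd;
  IntegerVector idx(Rf_allocVector(INTSXP, x.size()));
  idx.attr("dim") = xd;

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)H * W * C * n;
    double* os = out.begin() + (size_t)H * W * C * n;
    int* is = idx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)H * W * c;
      for (int ow = 0; ow < W; ++ow) {
        for (int oh = 0; oh < H; ++oh) {
          double best = -INFINITY; int besti = -1;
          int w0 = ow - pad, h0 = oh - pad;
          for (int dw = 0; dw < k; ++dw) {
            int wv = w0 + dw;
            if (wv < 0 || wv >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hv = h0 + dh;
              if (hv < 0 || hv >= H) continue;
              double v = xc[hv + (size_t)H * wv];
              if (v > best) { best = v; besti = hv + H * (wv + W * c); }
            }
          }
          os[(size_t)H * W * c + oh + (size_t)H * ow] = best;
          is[(size_t)H * W * c + oh + (size_t)H * ow] = besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector gout, IntegerVector idx) {
  IntegerVector xd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector gx(Rf_allocVector(REALSXP, gout.size()));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xd;
  size_t slice = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    const double* g = gout.begin() + slice * n;
    const int* is = idx.begin() + slice * n;
    double* gs = gx.begin() + slice * n;
    for (size_t i = 0; i < slice; ++i) gs[is[i]] += g[i];
  }
  return gx;
}

// Per-channel batch statistics (biased variance) over H, W, N.
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W, slice = hw * C;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + slice * n + hw * c;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (hw * N);
    mu[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = gamma * (x - mu) * invstd + beta, per channel.
// [[Rcpp::export(name = ".bn_apply")]]
NumericVector bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
                       NumericVector mu, NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W, slice = hw * C;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + slice * n + hw * c;
      double* q = y.begin() + slice * n + hw * c;
      double a = gamma[c] * invstd[c], b = beta[c] - mu[c] * a;
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * a + b;
    }
  return y;
}

// BN backward. In train mode (batch statistics):
//   gx = gamma*invstd * (g - mean(g) - xhat*mean(g*xhat)),
// in eval mode gx = gamma*invstd*g. Also returns dgamma = sum(g*xhat),
// dbeta = sum(g).
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector g, NumericVector gamma,
            NumericVector mu, NumericVector invstd, bool train) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W, slice = hw * C;
  double m = (double)hw * N;
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + slice * n + hw * c;
      const double* pg = g.begin() + slice * n + hw * c;
      for (size_t i = 0; i < hw; ++i) {
        double xhat = (px[i] - mu[c]) * invstd[c];
        sg += pg[i];
        sgx += pg[i] * xhat;
      }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    double a = gamma[c] * invstd[c];
    double mg = sg / m, mgx = sgx / m;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + slice * n + hw * c;
      const double* pg = g.begin() + slice * n + hw * c;
      double* pq = gx.begin() + slice * n + hw * c;
      if (train) {
        for (size_t i = 0; i < hw; ++i) {
          double xhat = (px[i] - mu[c]) * invstd[c];
          pq[i] = a * (pg[i] - mg - xhat * mgx);
        }
      } else {
        for (size_t i = 0; i < hw; ++i) pq[i] = a * pg[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// SiLU forward/backward, elementwise.
// [[Rcpp::export(name = ".silu_fwd")]]
NumericVector silu_fwd(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = fast_sigmoid(x[i]);
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export(name = ".silu_bwd")]]
NumericVector silu_bwd(NumericVector x, NumericVector g) {
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = fast_sigmoid(x[i]);
    gx[i] = g[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return gx;
}

// SiLU forward that also returns the sigmoid, so backward avoids exp.
// [[Rcpp::export(name = ".silu_fwd2")]]
List silu_fwd2(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  NumericVector s(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double si = fast_sigmoid(x[i]);
    s[i] = si;
    y[i] = x[i] * si;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export(name = ".silu_bwd2")]]
NumericVector silu_bwd2(NumericVector x, NumericVector s, NumericVector g) {
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    gx[i] = g[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  return gx;
}

// Channel-wise concatenation / slicing / nearest x2 resampling: plain
// memcpy-style kernels to avoid R-level index arithmetic on big arrays.

// [[Rcpp::export(name = ".concat_c")]]
NumericVector concat_c(List xs) {
  int m = xs.size();
  std::vector<NumericVector> v(m);
  int H = 0, W = 0, N = 0, Ctot = 0;
  for (int i = 0; i < m; ++i) {
    v[i] = as<NumericVector>(xs[i]);
    IntegerVector d = v[i].attr("dim");
    if (i == 0) { H = d[0]; W = d[1]; N = d[3]; }
    Ctot += d[2];
  }
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Ctot * N));
  out.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* dst = out.begin() + hw * Ctot * n;
    for (int i = 0; i < m; ++i) {
      IntegerVector d = v[i].attr("dim");
      size_t sz = hw * d[2];
      std::copy(v[i].begin() + sz * n, v[i].begin() + sz * (n + 1), dst);
      dst += sz;
    }
  }
  return out;
}

// Extract channels [from, from+len) (0-based).
// [[Rcpp::export(name = ".slice_c")]]
NumericVector slice_c(NumericVector x, int from, int len) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)H * W * len * N));
  out.attr("dim") = IntegerVector::create(H, W, len, N);
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + hw * (C * n + from), x.begin() + hw * (C * n + from + len),
              out.begin() + hw * len * n);
  return out;
}

// Scatter a channel-slice gradient back into a zero array of the full shape.
// [[Rcpp::export(name = ".slice_c_bwd")]]
NumericVector slice_c_bwd(NumericVector g, int from, int C) {
  IntegerVector d = g.attr("dim");
  int H = d[0], W = d[1], len = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(out.begin(), out.end(), 0.0);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    std::copy(g.begin() + hw * len * n, g.begin() + hw * len * (n + 1),
              out.begin() + hw * (C * n + from));
  return out;
}

// [[Rcpp::export(name = ".upsample2x_fwd")]]
NumericVector upsample2x_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)4 * H * W * C * N));
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* src = x.begin() + (size_t)H * W * cn;
    double* dst = out.begin() + (size_t)4 * H * W * cn;
    for (int w = 0; w < W; ++w) {
      const double* sc = src + (size_t)H * w;
      double* d0 = dst + (size_t)4 * H * w;
      double* d1 = d0 + 2 * H;
      for (int h = 0; h < H; ++h) {
        double vv = sc[h];
        d0[2 * h] = vv; d0[2 * h + 1] = vv;
        d1[2 * h] = vv; d1[2 * h + 1] = vv;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".upsample2x_bwd")]]
NumericVector upsample2x_bwd(NumericVector g) {
  IntegerVector d = g.attr("dim");
  int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* src = g.begin() + (size_t)H2 * W2 * cn;
    double* dst = out.begin() + (size_t)H * W * cn;
    for (int w = 0; w < W; ++w) {
      const double* s0 = src + (size_t)H2 * (2 * w);
      const double* s1 = src + (size_t)H2 * (2 * w + 1);
      double* dc = dst + (size_t)H * w;
      for (int h = 0; h < H; ++h)
        dc[h] = s0[2 * h] + s0[2 * h + 1] + s1[2 * h] + s1[2 * h + 1];
    }
  }
  return out;
}

// Greedy NMS on confidence-sorted corner boxes (n x 4, column-major).
// Returns 1-based indices of kept rows.
// [[Rcpp::export(name = ".nms_keep")]]
IntegerVector nms_keep(NumericMatrix boxes, double iou_thresh, int max_out) {
  int n = boxes.nrow();
  std::vector<char> alive(n, 1);
  std::vector<int> keep;
  const double* x1 = &boxes(0, 0);
  const double* y1 = &boxes(0, 1);
  const double* x2 = &boxes(0, 2);
  const double* y2 = &boxes(0, 3);
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    keep.push_back(i + 1);
    if ((int)keep.size() >= max_out) break;
    double ai = (x2[i] - x1[i]) * (y2[i] - y1[i]);
    for (int j = i + 1; j < n; ++j) {
      if (!alive[j]) continue;
      double iw = std::min(x2[i], x2[j]) - std::max(x1[i], x1[j]);
      if (iw <= 0) continue;
      double ih = std::min(y2[i], y2[j]) - std::max(y1[i], y1[j]);
      if (ih <= 0) continue;
      double inter = iw * ih;
      double u = ai + (x2[j] - x1[j]) * (y2[j] - y1[j]) - inter;
      if (u > 0 && inter / u > iou_thresh) alive[j] = 0;
    }
  }
  return wrap(keep);
}

// Package init: keep large-vector allocations in the heap instead of
// per-allocation mmap/munmap. The training loop allocates ~1 GB of
// short-lived activation arrays per optimizer step; without this, page
// faults dominate the runtime on a single CPU.
#include <malloc.h>
// [[Rcpp::export(name = ".tune_allocator")]]
void tune_allocator() {
#ifdef M_MMAP_MAX
  mallopt(M_MMAP_MAX, 0);
  mallopt(M_TRIM_THRESHOLD, -1);
#endif
}
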