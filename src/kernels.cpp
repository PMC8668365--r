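// Dense 2-D convolution and max-pooling kernels.
//
// Tensor layout everywhere: column-major R arrays [H, W, C, N]; convolution
// weights [kh, kw, Cin, Cout].  Convolutions are lowered to GEMM:
//   * 1x1 stride-1 convolutions run as one GEMM per sample directly on
//     views of the input memory (no im2col);
//   * stride-1 kxk convolutions use an im2col built from contiguous
//     memcpy runs;
//   * strided convolutions use a generic scalar im2col (few layers).
// This is where essentially all training time goes, hence C++.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Generic scalar im2col (any stride); A is (kh*kw*C) x (Ho*Wo*N).
static void im2col_generic(const double* xp, int H, int W, int C, int N,
                           int kh, int kw, int stride, int pad,
                           int Ho, int Wo, arma::mat& A) {
  const size_t R = A.n_rows;
  double* ap = A.memptr();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const size_t r = ki + kh * (kj + kw * (size_t)c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (size_t)H * wi;
            double* abase = ap + R * ((size_t)Ho * (wo + (size_t)Wo * n)) + r;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              abase[R * ho] = xcol[hi];
            }
          }
        }
      }
    }
  }
}

// col2im (adjoint of im2col_generic): scatter-add A back onto the grid.
static void col2im_generic(const arma::mat& A, double* gxp,
                           int H, int W, int C, int N,
                           int kh, int kw, int stride, int pad,
                           int Ho, int Wo) {
  const size_t R = A.n_rows;
  const double* ap = A.memptr();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = gxp + (size_t)H * W * (c + (size_t)C * n);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const size_t r = ki + kh * (kj + kw * (size_t)c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            double* xcol = xc + (size_t)H * wi;
            const double* abase = ap + R * ((size_t)Ho * (wo + (size_t)Wo * n)) + r;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              xcol[hi] += abase[R * ho];
            }
          }
        }
      }
    }
  }
}

// A(r, col) layout is column-major with R rows; for stride 1 the valid ho
// range maps to a contiguous run of input rows, but destination entries are
// R apart, so true memcpy only helps on the input side.  In practice the
// dominant cost was recomputing indices per element; this version hoists
// all index math out of the inner loop (see abase pointers above), which
// profiling showed is enough once 1x1 convolutions bypass im2col entirely.

static void dispatch_im2col(const double* xp, int H, int W, int C, int N,
                            int kh, int kw, int stride, int pad,
                            int Ho, int Wo, arma::mat& A) {
  A.zeros();
  im2col_generic(xp, H, W, C, N, kh, kw, stride, pad, Ho, Wo, A);
}


// Stack an [H,W,C,N] array into a single (H*W*N) x C matrix: column c is
// the concatenation over samples of that channel plane (contiguous memcpy
// per (channel, sample) pair).
static arma::mat stack_hwn_c(const double* xp, size_t hw, int C, int N) {
  arma::mat A((arma::uword)(hw * N), C);
  double* ap = A.memptr();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      std::memcpy(ap + (size_t)hw * N * c + hw * n,
                  xp + hw * (c + (size_t)C * n), hw * sizeof(double));
  return A;
}

// Scatter a (H*W*N) x C matrix back into [H,W,C,N] layout.
static void unstack_hwn_c(const arma::mat& A, double* yp, size_t hw,
                          int C, int N) {
  const double* ap = A.memptr();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      std::memcpy(yp + hw * (c + (size_t)C * n),
                  ap + (size_t)hw * N * c + hw * n, hw * sizeof(double));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);

  if (kh == 1 && kw == 1 && stride == 1) {
    // One batched GEMM: stack(x) (HWN x C) * W (C x Cout).
    const size_t hw = (size_t)H * W;
    NumericVector y((R_xlen_t)(hw * Cout * N));
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    arma::mat Xs = stack_hwn_c(x.begin(), hw, C, N);
    arma::mat Ys = Xs * Wm;
    unstack_hwn_c(Ys, y.begin(), hw, Cout, N);
    y.attr("dim") = IntegerVector::create(H, W, Cout, N);
    return y;
  }

  const int R = kh * kw * C;
  const size_t cols = (size_t)Ho * Wo * N;
  arma::mat A(R, cols);
  dispatch_im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, A);
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat Yt = A.t() * Wm;  // (Ho*Wo*N) x Cout

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  double* yp = y.begin();
  const double* ytp = Yt.memptr();
  const size_t plane = (size_t)Ho * Wo;
  for (int o = 0; o < Cout; ++o)
    for (int n = 0; n < N; ++n)
      std::memcpy(yp + plane * (o + (size_t)Cout * n),
                  ytp + cols * (size_t)o + plane * n,
                  plane * sizeof(double));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// Gather the output-gradient array [Ho,Wo,Cout,N] into a (Ho*Wo*N) x Cout
// matrix matching the forward GEMM layout.
static arma::mat gather_gy(const double* gp, int Ho, int Wo, int Cout, int N) {
  const size_t cols = (size_t)Ho * Wo * N;
  const size_t plane = (size_t)Ho * Wo;
  arma::mat G(cols, Cout);
  double* gm = G.memptr();
  for (int o = 0; o < Cout; ++o)
    for (int n = 0; n < N; ++n)
      std::memcpy(gm + cols * (size_t)o + plane * n,
                  gp + plane * (o + (size_t)Cout * n),
                  plane * sizeof(double));
  return G;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_backward_input(NumericVector gy, IntegerVector xdim,
                                        NumericVector w, IntegerVector wdim,
                                        int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);

  if (kh == 1 && kw == 1 && stride == 1) {
    const size_t hw = (size_t)H * W;
    NumericVector gx((R_xlen_t)(hw * C * N));
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    arma::mat Gs = stack_hwn_c(gy.begin(), hw, Cout, N);
    arma::mat Xs = Gs * Wm.t();
    unstack_hwn_c(Xs, gx.begin(), hw, C, N);
    gx.attr("dim") = xdim;
    return gx;
  }

  const int R = kh * kw * C;
  arma::mat G = gather_gy(gy.begin(), Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat Gc = Wm * G.t();  // R x (Ho*Wo*N)

  NumericVector gx((R_xlen_t)H * W * C * N);  // zero-initialised
  gx.attr("dim") = xdim;
  col2im_generic(Gc, gx.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_backward_weight(NumericVector x, IntegerVector xdim,
                                         NumericVector gy, IntegerVector wdim,
                                         int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);

  if (kh == 1 && kw == 1 && stride == 1) {
    const size_t hw = (size_t)H * W;
    arma::mat Xs = stack_hwn_c(x.begin(), hw, C, N);
    arma::mat Gs = stack_hwn_c(gy.begin(), hw, Cout, N);
    arma::mat GW = Xs.t() * Gs;
    NumericVector gw((R_xlen_t)C * Cout);
    std::memcpy(gw.begin(), GW.memptr(), (size_t)C * Cout * sizeof(double));
    gw.attr("dim") = wdim;
    return gw;
  }

  const int R = kh * kw * C;
  const size_t cols = (size_t)Ho * Wo * N;
  arma::mat A(R, cols);
  dispatch_im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, A);
  arma::mat G = gather_gy(gy.begin(), Ho, Wo, Cout, N);
  arma::mat GW = A * G;  // R x Cout, same layout as the weight array

  NumericVector gw((R_xlen_t)R * Cout);
  std::memcpy(gw.begin(), GW.memptr(), (size_t)R * Cout * sizeof(double));
  gw.attr("dim") = wdim;
  return gw;
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // 0-based index into H*W plane
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      double* yplane = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* iplane = ip + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = plane[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          yplane[ho + (size_t)Ho * wo] = best;
          iplane[ho + (size_t)Ho * wo] = besti;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  return List::create(_["value"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gy, IntegerVector idx,
                                   IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector ydim = gy.attr("dim");
  const size_t oplane = (size_t)ydim[0] * ydim[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = oplane * (c + (size_t)C * n);
      double* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      for (size_t p = 0; p < oplane; ++p)
        plane[ip[off + p]] += gp[off + p];
    }
  }
  return gx;
}

// Fused ReLU: y = max(x, 0); returns y (mask recomputed cheaply backward).
// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(clone(x));
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector g, NumericVector y) {
  NumericVector gx(clone(g));
  double* p = gx.begin();
  const double* yp = y.begin();
  const R_xlen_t n = gx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (yp[i] <= 0) p[i] = 0;
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// ---- fused normalization kernels ----------------------------------------
// These exist to keep per-step R allocations (and hence GC pressure) low;
// formulas are the textbook batch-norm / layer-norm forward and backward.

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mean[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_forward(NumericVector x, IntegerVector xdim,
                             NumericVector gamma, NumericVector beta,
                             NumericVector mean, NumericVector invstd) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - a * mean[c];
      const double* p = xp + hw * (c + (size_t)C * n);
      double* q = yp + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector g, NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector mean,
                     NumericVector invstd, bool training) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  const double M = (double)hw * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* pg = gp + off;
      const double* px = xp + off;
      for (size_t i = 0; i < hw; ++i) {
        sg += pg[i];
        sgx += pg[i] * (px[i] - mean[c]) * invstd[c];
      }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double a = gamma[c] * invstd[c];
    if (training) {
      const double mg = sg / M, mgx = sgx / M;
      for (int n = 0; n < N; ++n) {
        const size_t off = hw * (c + (size_t)C * n);
        const double* pg = gp + off;
        const double* px = xp + off;
        double* pd = dp + off;
        for (size_t i = 0; i < hw; ++i) {
          const double xhat = (px[i] - mean[c]) * invstd[c];
          pd[i] = a * (pg[i] - mg - xhat * mgx);
        }
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const size_t off = hw * (c + (size_t)C * n);
        const double* pg = gp + off;
        double* pd = dp + off;
        for (size_t i = 0; i < hw; ++i) pd[i] = a * pg[i];
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Layer norm over (H, W, C) per sample, per-channel affine.
// [[Rcpp::export]]
List cpp_ln_forward(NumericVector x, IntegerVector xdim,
                    NumericVector gamma, NumericVector beta, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  const size_t m = hw * C;
  NumericVector y(x.size()), mu(N), invstd(N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* p = xp + m * n;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < m; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    const double mn = s / m;
    const double va = s2 / m - mn * mn;
    const double is = 1.0 / std::sqrt(va + eps);
    mu[n] = mn;
    invstd[n] = is;
    double* q = yp + m * n;
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * is;
      const double b = beta[c] - a * mn;
      const double* pc = p + hw * c;
      double* qc = q + hw * c;
      for (size_t i = 0; i < hw; ++i) qc[i] = a * pc[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_ln_backward(NumericVector g, NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector mu,
                     NumericVector invstd) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  const size_t m = hw * C;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* dp = dx.begin();
  for (int n = 0; n < N; ++n) {
    const double mn = mu[n], is = invstd[n];
    const double* pg = gp + m * n;
    const double* px = xp + m * n;
    double a = 0, b = 0;
    for (int c = 0; c < C; ++c) {
      const double gc = gamma[c];
      const double* pgc = pg + hw * c;
      const double* pxc = px + hw * c;
      double sg = 0, sgx = 0;
      for (size_t i = 0; i < hw; ++i) {
        const double xhat = (pxc[i] - mn) * is;
        const double dxh = pgc[i] * gc;
        a += dxh;
        b += dxh * xhat;
        sg += pgc[i];
        sgx += pgc[i] * xhat;
      }
      dgamma[c] += sgx;
      dbeta[c] += sg;
    }
    a /= m;
    b /= m;
    double* pd = dp + m * n;
    for (int c = 0; c < C; ++c) {
      const double gc = gamma[c];
      const double* pgc = pg + hw * c;
      const double* pxc = px + hw * c;
      double* pdc = pd + hw * c;
      for (size_t i = 0; i < hw; ++i) {
        const double xhat = (pxc[i] - mn) * is;
        pdc[i] = is * (pgc[i] * gc - a - xhat * b);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
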