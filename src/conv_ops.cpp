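// Convolution and pooling kernels for the segmentation network.
// Layout: feature maps are (H, W, C, N) column-major arrays (R native);
// conv weights are (kh, kw, Cin, Cout). Stride is always 1; padding is
// symmetric zero padding, so odd kernels with pad = (k-1)/2 preserve H, W.
//
// Convolution is computed as a sum over kernel offsets of shifted GEMMs:
//   Y = sum_{di,dj} shift(X, di, dj) %*% W[di, dj, , ]
// which keeps peak memory at one HW x Cin buffer instead of a full im2col
// patch matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::cube pad_cube(const double* x, int H, int W, int C, int p) {
  arma::cube xp(H + 2 * p, W + 2 * p, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat ch(const_cast<double*>(x) + (std::size_t)c * H * W, H, W,
                 false, true);
    xp.slice(c).submat(p, p, p + H - 1, p + W - 1) = ch;
  }
  return xp;
}

// copy the (di, dj)-shifted H x W window of each channel into an HW x C matrix
static inline void gather_shift(const arma::cube& xp, int di, int dj, int H,
                                int W, arma::mat& out) {
  const int C = xp.n_slices;
  for (int c = 0; c < C; ++c) {
    arma::mat win = xp.slice(c).submat(di, dj, di + H - 1, dj + W - 1);
    std::copy(win.begin(), win.end(), out.colptr(c));
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("kernel input channels do not match feature map");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const std::size_t hw = (std::size_t)Ho * Wo;

  if (kh == 1 && kw == 1 && pad == 0) {
    // 1x1 convolution: each image is already an HW x Cin matrix in memory
    arma::mat wm(const_cast<double*>(w.begin()), Cin, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat xn(const_cast<double*>(x.begin()) + (std::size_t)n * hw * Cin,
                   hw, Cin, false, true);
      arma::mat yn(y.begin() + (std::size_t)n * hw * Cout, hw, Cout, false,
                   true);
      yn = xn * wm;
      for (int o = 0; o < Cout; ++o) yn.col(o) += b[o];
    }
    return y;
  }

  // pad all images/channels at once; slice order (c, n) matches the layout
  arma::cube xp = pad_cube(x.begin(), H, W, Cin * N, pad);
  arma::mat xs(hw * N, Cin);
  arma::mat ybig(hw * N, Cout, arma::fill::zeros);
  for (int dj = 0; dj < kw; ++dj) {
    for (int di = 0; di < kh; ++di) {
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cin; ++c) {
          arma::mat win = xp.slice(c + (std::size_t)Cin * n)
                              .submat(di, dj, di + Ho - 1, dj + Wo - 1);
          std::copy(win.begin(), win.end(), xs.colptr(c) + n * hw);
        }
      arma::mat wm(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int ci = 0; ci < Cin; ++ci)
          wm(ci, o) = w[di + kh * (dj + kw * (ci + (std::size_t)Cin * o))];
      ybig += xs * wm;
    }
  }
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* src = ybig.colptr(o) + n * hw;
      double* dst = y.begin() + ((std::size_t)n * Cout + o) * hw;
      for (std::size_t k = 0; k < hw; ++k) dst[k] = src[k] + b[o];
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;

  NumericVector gx((R_xlen_t)H * W * Cin * N);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  const std::size_t hw = (std::size_t)Ho * Wo;

  if (kh == 1 && kw == 1 && pad == 0) {
    arma::mat wm(const_cast<double*>(w.begin()), Cin, Cout, false, true);
    arma::mat gwm(gw.begin(), Cin, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat xn(const_cast<double*>(x.begin()) + (std::size_t)n * hw * Cin,
                   hw, Cin, false, true);
      arma::mat gn(const_cast<double*>(gy.begin()) + (std::size_t)n * hw * Cout,
                   hw, Cout, false, true);
      arma::mat gxn(gx.begin() + (std::size_t)n * hw * Cin, hw, Cin, false,
                    true);
      gwm += xn.t() * gn;
      gxn = gn * wm.t();
      for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(gn.col(o));
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  arma::cube xp = pad_cube(x.begin(), H, W, Cin * N, pad);
  arma::cube gxp(H + 2 * pad, W + 2 * pad, Cin * N, arma::fill::zeros);
  arma::mat xs(hw * N, Cin);
  arma::mat g(hw * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* src = gy.begin() + ((std::size_t)n * Cout + o) * hw;
      std::copy(src, src + hw, g.colptr(o) + n * hw);
      for (std::size_t k = 0; k < hw; ++k) gb[o] += src[k];
    }
  for (int dj = 0; dj < kw; ++dj) {
    for (int di = 0; di < kh; ++di) {
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cin; ++c) {
          arma::mat win = xp.slice(c + (std::size_t)Cin * n)
                              .submat(di, dj, di + Ho - 1, dj + Wo - 1);
          std::copy(win.begin(), win.end(), xs.colptr(c) + n * hw);
        }
      arma::mat gwm = xs.t() * g;            // Cin x Cout
      arma::mat wm(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int ci = 0; ci < Cin; ++ci) {
          gw[di + kh * (dj + kw * (ci + (std::size_t)Cin * o))] += gwm(ci, o);
          wm(ci, o) = w[di + kh * (dj + kw * (ci + (std::size_t)Cin * o))];
        }
      arma::mat gxs = g * wm.t();            // (N*HoWo) x Cin
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cin; ++c) {
          arma::mat gwin(gxs.colptr(c) + n * hw, Ho, Wo, false, true);
          gxp.slice(c + (std::size_t)Cin * n)
              .submat(di, dj, di + Ho - 1, dj + Wo - 1) += gwin;
        }
    }
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cin; ++c) {
      arma::mat dst(gx.begin() + ((std::size_t)n * Cin + c) * H * W, H, W,
                    false, true);
      dst = gxp.slice(c + (std::size_t)Cin * n)
                .submat(pad, pad, pad + H - 1, pad + W - 1);
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled map and the 1-based linear index
// (within each H x W plane) of the winning element, for the backward scatter.
// Ties break toward the earliest element in column-major order.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");

  std::size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pl = x.begin() + ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int base = 2 * i + H * 2 * j;
          int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          for (int k = 1; k < 4; ++k)
            if (pl[cand[k]] > pl[best]) best = cand[k];
          y[q] = pl[best];
          idx[q] = best + 1;
          ++q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector idx, int H,
                              int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* pl = gx.begin() + ((std::size_t)n * C + c) * H * W;
      for (int k = 0; k < Ho * Wo; ++k, ++q) pl[idx[q] - 1] += gy[q];
    }
  return gx;
}

// Directed nearest-point distances from each row of `a` to the point set `b`,
// in physical units (points are already scaled by spacing). Brute force over
// pairs, chunked implicitly by the column loop.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// per-channel sums and sums of squares over (H, W, N)
// [[Rcpp::export]]
List cpp_chan_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  NumericVector s(C), ss(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)n * C + c) * hw;
      double a = 0.0, b = 0.0;
      for (std::size_t k = 0; k < hw; ++k) {
        a += p[k];
        b += p[k] * p[k];
      }
      s[c] += a;
      ss[c] += b;
    }
  return List::create(_["sum"] = s, _["sumsq"] = ss);
}

// y = (x - mu_c) * istd_c * gamma_c + beta_c
// [[Rcpp::export]]
NumericVector cpp_bn_fw(NumericVector x, NumericVector gamma,
                        NumericVector beta, NumericVector mu,
                        NumericVector istd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)n * C + c) * hw;
      double* q = y.begin() + ((std::size_t)n * C + c) * hw;
      const double a = istd[c] * gamma[c];
      const double b = beta[c] - mu[c] * a;
      for (std::size_t k = 0; k < hw; ++k) q[k] = p[k] * a + b;
    }
  return y;
}

// Training-mode batch-norm backward. Returns gx and the gamma/beta grads.
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector gy, NumericVector gamma,
               NumericVector mu, NumericVector istd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  const double M = (double)hw * N;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)n * C + c) * hw;
      const double* g = gy.begin() + ((std::size_t)n * C + c) * hw;
      double a = 0.0, b = 0.0;
      for (std::size_t k = 0; k < hw; ++k) {
        const double xh = (p[k] - mu[c]) * istd[c];
        a += g[k] * xh;
        b += g[k];
      }
      dgamma[c] += a;
      dbeta[c] += b;
    }
  for (int c = 0; c < C; ++c) {
    s1[c] = dbeta[c] * gamma[c] / M;       // mean of gxhat
    s2[c] = dgamma[c] * gamma[c] / M;      // mean of gxhat * xhat
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)n * C + c) * hw;
      const double* g = gy.begin() + ((std::size_t)n * C + c) * hw;
      double* q = gx.begin() + ((std::size_t)n * C + c) * hw;
      for (std::size_t k = 0; k < hw; ++k) {
        const double xh = (p[k] - mu[c]) * istd[c];
        q[k] = (g[k] * gamma[c] - s1[c] - xh * s2[c]) * istd[c];
      }
    }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
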