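// Low-level kernels for the segmentation network.
// Activation layout everywhere: column-major [H, W, C, N] (R array order).
// Convolution weights: [k, k, Cin, Cout]; stride is always 1 with "same"
// padding pad = dilation * (k - 1) / 2, so spatial dims are preserved.

#include <RcppArmadillo.h>
using namespace Rcpp;

static Rcpp::Dimension dim4(int a, int b, int c, int d) {
  return Rcpp::Dimension(IntegerVector::create(a, b, c, d));
}

static void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dv = x.attr("dim");
  if (dv.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dv[i];
}

// Direct convolution via one GEMM per sample plus shift-accumulate.
// For output pixel p and kernel tap t with spatial offset d(t):
//   y[p, co] = sum_t sum_ci x[p + d(t), ci] * w[t, ci, co]
// so Z = X * Wall (with Wall(ci, t + k2*co) = w[t, ci, co]) holds every
// tap's contribution and the taps are folded in with shifted adds. This
// avoids materializing the much larger im2col matrix.

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int dilation) {
  int xd[4];
  dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight/input channel mismatch");
  const int k2 = k * k, off = (k - 1) / 2;
  const size_t M = (size_t)H * W;
  NumericVector y(dim4(H, W, Cout, N));
  arma::mat Wall(Cin, k2 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int t = 0; t < k2; ++t)
        Wall(ci, t + k2 * co) = w[t + k2 * (ci + (size_t)Cin * co)];
  arma::mat Z(M, k2 * Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double *>(x.begin()) + M * Cin * n, M, Cin,
                 false, true);
    Z = Xn * Wall;
    for (int co = 0; co < Cout; ++co) {
      double *yc = y.begin() + M * (co + (size_t)Cout * n);
      std::fill(yc, yc + M, b[co]);
      for (int t = 0; t < k2; ++t) {
        const int dh = (t % k - off) * dilation;
        const int dw = (t / k - off) * dilation;
        const double *zc = Z.colptr(t + k2 * co);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int wcol = 0; wcol < W; ++wcol) {
          const int iw = wcol + dw;
          if (iw < 0 || iw >= W) continue;
          double *d = yc + (size_t)H * wcol;
          const double *src = zc + (size_t)H * iw + dh;
          for (int h = h0; h < h1; ++h) d[h] += src[h];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int dilation) {
  int xd[4];
  dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int k2 = k * k, off = (k - 1) / 2;
  const size_t M = (size_t)H * W;
  NumericVector dx(dim4(H, W, Cin, N));
  NumericVector dw(dim4(k, k, Cin, Cout));
  NumericVector db(Cout);
  // Wr(t + k2*co, ci) = w[t, ci, co]
  arma::mat Wr(k2 * Cout, Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int t = 0; t < k2; ++t)
        Wr(t + k2 * co, ci) = w[t + k2 * (ci + (size_t)Cin * co)];
  arma::mat dWflat(Cin, k2 * Cout, arma::fill::zeros);
  arma::mat dYs(M, k2 * Cout);
  for (int n = 0; n < N; ++n) {
    // dYs[p, t + k2*co] = dy[p - d(t), co] (zero outside)
    for (int co = 0; co < Cout; ++co) {
      const double *gc = dy.begin() + M * (co + (size_t)Cout * n);
      double s = 0;
      for (size_t i = 0; i < M; ++i) s += gc[i];
      db[co] += s;
      for (int t = 0; t < k2; ++t) {
        const int dh = (t % k - off) * dilation;
        const int dw2 = (t / k - off) * dilation;
        double *dst = dYs.colptr(t + k2 * co);
        const int h0 = std::max(0, dh), h1 = std::min(H, H + dh);
        for (int wcol = 0; wcol < W; ++wcol) {
          const int iw = wcol - dw2;
          double *d = dst + (size_t)H * wcol;
          if (iw < 0 || iw >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double *src = gc + (size_t)H * iw - dh;
          if (h0 > 0) std::fill(d, d + h0, 0.0);
          for (int h = h0; h < h1; ++h) d[h] = src[h];
          if (h1 < H) std::fill(d + h1, d + H, 0.0);
        }
      }
    }
    arma::mat Xn(const_cast<double *>(x.begin()) + M * Cin * n, M, Cin,
                 false, true);
    arma::mat dXn(dx.begin() + M * Cin * n, M, Cin, false, true);
    dXn = dYs * Wr;
    dWflat += Xn.t() * dYs;
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int t = 0; t < k2; ++t)
        dw[t + k2 * (ci + (size_t)Cin * co)] = dWflat(ci, t + k2 * co);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Transposed convolution, kernel 2x2, stride 2: output is (2H, 2W, Cout, N).
// y[2h+a, 2w+b, co] = sum_ci x[h, w, ci] * w[a, b, ci, co] + bias[co]
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  int xd[4];
  dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != Cin) stop("bad convt weights");
  const int M = H * W, Ho = 2 * H, Wo = 2 * W;
  NumericVector y(dim4(Ho, Wo, Cout, N));
  for (int a = 0; a < 2; ++a) {
    for (int b2 = 0; b2 < 2; ++b2) {
      arma::mat Wab(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wab(ci, co) = w[a + 2 * (b2 + 2 * (ci + (size_t)Cin * co))];
      for (int n = 0; n < N; ++n) {
        arma::mat Xm(const_cast<double *>(x.begin()) + (size_t)M * Cin * n, M,
                     Cin, false, true);
        arma::mat Yab = Xm * Wab; // M x Cout
        double *yp = y.begin() + (size_t)Ho * Wo * Cout * n;
        for (int co = 0; co < Cout; ++co) {
          const double *src = Yab.colptr(co);
          double *yc = yp + (size_t)Ho * Wo * co;
          const double bias = b[co];
          for (int w2 = 0; w2 < W; ++w2)
            for (int h = 0; h < H; ++h)
              yc[(2 * h + a) + Ho * (2 * w2 + b2)] = src[h + H * w2] + bias;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int xd[4];
  dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int M = H * W, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(dim4(H, W, Cin, N));
  NumericVector dw(dim4(2, 2, Cin, Cout));
  NumericVector db(Cout);
  for (int a = 0; a < 2; ++a) {
    for (int b2 = 0; b2 < 2; ++b2) {
      arma::mat Wab(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wab(ci, co) = w[a + 2 * (b2 + 2 * (ci + (size_t)Cin * co))];
      arma::mat dWab(Cin, Cout, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        arma::mat Xm(const_cast<double *>(x.begin()) + (size_t)M * Cin * n, M,
                     Cin, false, true);
        arma::mat dYab(M, Cout);
        const double *dyp = dy.begin() + (size_t)Ho * Wo * Cout * n;
        for (int co = 0; co < Cout; ++co) {
          double *dst = dYab.colptr(co);
          const double *dyc = dyp + (size_t)Ho * Wo * co;
          double s = 0.0;
          for (int w2 = 0; w2 < W; ++w2)
            for (int h = 0; h < H; ++h) {
              const double v = dyc[(2 * h + a) + Ho * (2 * w2 + b2)];
              dst[h + H * w2] = v;
              s += v;
            }
          db[co] += s;
        }
        arma::mat dXm(dx.begin() + (size_t)M * Cin * n, M, Cin, false, true);
        dXm += dYab * Wab.t();
        dWab += Xm.t() * dYab;
      }
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          dw[a + 2 * (b2 + 2 * (ci + (size_t)Cin * co))] = dWab(ci, co);
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and the 1-based flat index
// (into x) of each maximum for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int xd[4];
  dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(dim4(Ho, Wo, C, N));
  IntegerVector idx(dim4(Ho, Wo, C, N));
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t best = (size_t)(2 * h) + H * (size_t)(2 * w);
          double bv = xc[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int j = 0; j < 3; ++j)
            if (xc[cand[j]] > bv) {
              bv = xc[cand[j]];
              best = cand[j];
            }
          y[o] = bv;
          idx[o] = (int)(base + best) + 1;
          ++o;
        }
    }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx(dim4(xdim[0], xdim[1], xdim[2], xdim[3]));
  const int n = dy.size();
  for (int i = 0; i < n; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// ---- batch normalization (per-channel over H, W, N) ------------------------

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  int xd[4];
  dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t M = (size_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + M * (c + (size_t)C * n);
      for (size_t i = 0; i < M; ++i) {
        s += xc[i];
        s2 += xc[i] * xc[i];
      }
    }
    const double m = (double)M * N;
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
  }
  return List::create(Named("mean") = mu, Named("var") = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_fwd(NumericVector x, NumericVector gamma,
                         NumericVector beta, NumericVector mu,
                         NumericVector invstd) {
  int xd[4];
  dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t M = (size_t)H * W;
  NumericVector y(dim4(H, W, C, N));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + M * (c + (size_t)C * n);
      double *yc = y.begin() + M * (c + (size_t)C * n);
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - a * mu[c];
      for (size_t i = 0; i < M; ++i) yc[i] = a * xc[i] + b;
    }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector invstd, bool training) {
  int xd[4];
  dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t M = (size_t)H * W;
  const double m = (double)M * N;
  NumericVector dx(dim4(H, W, C, N));
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s_dy = 0, s_dyxh = 0;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + M * (c + (size_t)C * n);
      const double *gc = dy.begin() + M * (c + (size_t)C * n);
      for (size_t i = 0; i < M; ++i) {
        s_dy += gc[i];
        s_dyxh += gc[i] * (xc[i] - mu[c]) * invstd[c];
      }
    }
    dbeta[c] = s_dy;
    dgamma[c] = s_dyxh;
    const double mean_dxh = gamma[c] * s_dy / m;
    const double mean_dxh_xh = gamma[c] * s_dyxh / m;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + M * (c + (size_t)C * n);
      const double *gc = dy.begin() + M * (c + (size_t)C * n);
      double *dc = dx.begin() + M * (c + (size_t)C * n);
      for (size_t i = 0; i < M; ++i) {
        const double dxh = gamma[c] * gc[i];
        if (training) {
          const double xh = (xc[i] - mu[c]) * invstd[c];
          dc[i] = invstd[c] * (dxh - mean_dxh - xh * mean_dxh_xh);
        } else {
          dc[i] = invstd[c] * dxh;
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
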