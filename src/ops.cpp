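#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are R arrays with dim (H, W, C, N), column-major.
// Conv weights are R arrays with dim (K, K, Cin, Cout); flattening the first
// three dims column-major gives row r = ki + K*(kj + K*c) of the GEMM matrix.

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static void im2col(const double* src, int H, int W, int C, int K, int stride,
                   int pad, int Ho, int Wo, arma::mat& cols) {
  const arma::uword nr = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    const double* ch = src + (size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        double* dst = cols.memptr() + (ki + K * (kj + K * c));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          const bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = ch[hi + (size_t)H * wi];
            dst[(size_t)(ho + (size_t)Ho * wo) * nr] = v;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& cols, int H, int W, int C, int K,
                       int stride, int pad, int Ho, int Wo, double* dst) {
  const arma::uword nr = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    double* ch = dst + (size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const double* srcp = cols.memptr() + (ki + K * (kj + K * c));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            ch[hi + (size_t)H * wi] += srcp[(size_t)(ho + (size_t)Ho * wo) * nr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weight must be a 4-d array (K, K, Cin, Cout)");
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != K) stop("non-square kernel");
  if (Cin != C) stop("input channels do not match weight");
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output would be empty");
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wmat(const_cast<double*>(w.begin()), (size_t)K * K * Cin, Cout, false, true);
  arma::mat cols((size_t)K * K * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad, Ho, Wo, cols);
    arma::mat ymat(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
    ymat = cols.t() * wmat;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat wmat(const_cast<double*>(w.begin()), (size_t)K * K * Cin, Cout, false, true);
  arma::mat dwmat(dw.begin(), (size_t)K * K * Cin, Cout, false, true);
  arma::mat cols((size_t)K * K * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad, Ho, Wo, cols);
    arma::mat dymat(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Cout, false, true);
    dwmat += cols * dymat;
    if (need_dx) {
      arma::mat dcols = wmat * dymat.t();
      col2im_acc(dcols, H, W, C, K, stride, pad, Ho, Wo,
                 dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int K, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output would be empty");
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // argmax linear offset within the sample slice
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * Ho * Wo * C;
    int* is = idx.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      const double* ch = xs + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < K; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = ch[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi + H * W * c; }
            }
          }
          const size_t o = (size_t)(ho + (size_t)Ho * wo) + (size_t)Ho * Wo * c;
          ys[o] = best;
          is[o] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              int H, int W, int C) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t per = (size_t)Ho * Wo * C;
  for (int n = 0; n < N; ++n) {
    double* dxs = dx.begin() + (size_t)n * H * W * C;
    const double* dys = dy.begin() + (size_t)n * per;
    const int* is = idx.begin() + (size_t)n * per;
    for (size_t o = 0; o < per; ++o)
      if (is[o] >= 0) dxs[is[o]] += dys[o];
  }
  return dx;
}

// 2x2 average pooling, stride 1, no padding: output (H-1, W-1).
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = H - 1, Wo = W - 1;
  if (Ho < 1 || Wo < 1) stop("input too small for 2x2 pooling");
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* ch = x.begin() + s * H * W;
    double* yo = y.begin() + s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yo[ho + (size_t)Ho * wo] = 0.25 * (ch[ho + (size_t)H * wo] +
                                           ch[ho + 1 + (size_t)H * wo] +
                                           ch[ho + (size_t)H * (wo + 1)] +
                                           ch[ho + 1 + (size_t)H * (wo + 1)]);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    double* ch = dx.begin() + s * H * W;
    const double* dyo = dy.begin() + s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * dyo[ho + (size_t)Ho * wo];
        ch[ho + (size_t)H * wo] += g;
        ch[ho + 1 + (size_t)H * wo] += g;
        ch[ho + (size_t)H * (wo + 1)] += g;
        ch[ho + 1 + (size_t)H * (wo + 1)] += g;
      }
  }
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* ch = x.begin() + s * H * W;
    double* yo = y.begin() + s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* col = ch + (size_t)H * (wo / 2);
      for (int ho = 0; ho < Ho; ++ho)
        yo[ho + (size_t)Ho * wo] = col[ho / 2];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    double* ch = dx.begin() + s * H * W;
    const double* dyo = dy.begin() + s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      double* col = ch + (size_t)H * (wo / 2);
      for (int ho = 0; ho < Ho; ++ho)
        col[ho / 2] += dyo[ho + (size_t)Ho * wo];
    }
  }
  return dx;
}

// ---- fused elementwise/per-channel kernels (hot path of training) --------

// [[Rcpp::export]]
List cpp_bn_fwd_train(NumericVector z, NumericVector gamma, NumericVector beta,
                      double eps) {
  int H, W, C, N;
  get_dims4(z, H, W, C, N);
  const size_t hw = (size_t)H * W, chw = hw * C;
  NumericVector mu(C), var(C);
  for (int n = 0; n < N; ++n) {
    const double* zs = z.begin() + (size_t)n * chw;
    for (int c = 0; c < C; ++c) {
      const double* ch = zs + (size_t)c * hw;
      double s = 0, s2 = 0;
      for (size_t k = 0; k < hw; ++k) { s += ch[k]; s2 += ch[k] * ch[k]; }
      mu[c] += s;
      var[c] += s2;
    }
  }
  const double nel = (double)hw * N;
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] /= nel;
    var[c] = var[c] / nel - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector xhat(z.size()), y(z.size());
  xhat.attr("dim") = z.attr("dim");
  y.attr("dim") = z.attr("dim");
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * chw;
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
      const double* zc = z.begin() + off + (size_t)c * hw;
      double* xc = xhat.begin() + off + (size_t)c * hw;
      double* yc = y.begin() + off + (size_t)c * hw;
      for (size_t k = 0; k < hw; ++k) {
        const double v = (zc[k] - m) * is;
        xc[k] = v;
        yc[k] = g * v + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_fwd_eval(NumericVector z, NumericVector gamma,
                              NumericVector beta, NumericVector rm,
                              NumericVector rv, double eps) {
  int H, W, C, N;
  get_dims4(z, H, W, C, N);
  const size_t hw = (size_t)H * W, chw = hw * C;
  NumericVector y(z.size());
  y.attr("dim") = z.attr("dim");
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * chw;
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] / std::sqrt(rv[c] + eps);
      const double sh = beta[c] - rm[c] * sc;
      const double* zc = z.begin() + off + (size_t)c * hw;
      double* yc = y.begin() + off + (size_t)c * hw;
      for (size_t k = 0; k < hw; ++k) yc[k] = sc * zc[k] + sh;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
                NumericVector gamma) {
  int H, W, C, N;
  get_dims4(dy, H, W, C, N);
  const size_t hw = (size_t)H * W, chw = hw * C;
  NumericVector dgamma(C), dbeta(C), m1(C), m2(C);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * chw;
    for (int c = 0; c < C; ++c) {
      const double* dc = dy.begin() + off + (size_t)c * hw;
      const double* xc = xhat.begin() + off + (size_t)c * hw;
      double sg = 0, sb = 0;
      for (size_t k = 0; k < hw; ++k) { sg += dc[k] * xc[k]; sb += dc[k]; }
      dgamma[c] += sg;
      dbeta[c] += sb;
    }
  }
  const double nel = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    m1[c] = gamma[c] * dbeta[c] / nel;
    m2[c] = gamma[c] * dgamma[c] / nel;
  }
  NumericVector dz(dy.size());
  dz.attr("dim") = dy.attr("dim");
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * chw;
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c], is = invstd[c], a1 = m1[c], a2 = m2[c];
      const double* dc = dy.begin() + off + (size_t)c * hw;
      const double* xc = xhat.begin() + off + (size_t)c * hw;
      double* oc = dz.begin() + off + (size_t)c * hw;
      for (size_t k = 0; k < hw; ++k) {
        oc[k] = is * (g * dc[k] - a1 - xc[k] * a2);
      }
    }
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_silu_fwd(NumericVector a) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  for (R_xlen_t k = 0; k < a.size(); ++k) {
    y[k] = a[k] / (1.0 + std::exp(-a[k]));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_silu_bwd(NumericVector a, NumericVector dy) {
  NumericVector dx(a.size());
  dx.attr("dim") = a.attr("dim");
  for (R_xlen_t k = 0; k < a.size(); ++k) {
    const double s = 1.0 / (1.0 + std::exp(-a[k]));
    dx[k] = dy[k] * s * (1.0 + a[k] * (1.0 - s));
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_bias_add(NumericVector z, NumericVector b) {
  int H, W, C, N;
  get_dims4(z, H, W, C, N);
  const size_t hw = (size_t)H * W, chw = hw * C;
  NumericVector y(z.size());
  y.attr("dim") = z.attr("dim");
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * chw;
    for (int c = 0; c < C; ++c) {
      const double bc = b[c];
      const double* zc = z.begin() + off + (size_t)c * hw;
      double* yc = y.begin() + off + (size_t)c * hw;
      for (size_t k = 0; k < hw; ++k) yc[k] = zc[k] + bc;
    }
  }
  return y;
}

// SiLU backward from the cached forward sigmoid (avoids recomputing exp).
// [[Rcpp::export]]
NumericVector cpp_silu_bwd_cached(NumericVector a, NumericVector s,
                                  NumericVector dy) {
  NumericVector dx(a.size());
  dx.attr("dim") = a.attr("dim");
  for (R_xlen_t k = 0; k < a.size(); ++k) {
    dx[k] = dy[k] * s[k] * (1.0 + a[k] * (1.0 - s[k]));
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_silu_fwd_cache(NumericVector a) {
  NumericVector y(a.size()), s(a.size());
  y.attr("dim") = a.attr("dim");
  for (R_xlen_t k = 0; k < a.size(); ++k) {
    const double sk = 1.0 / (1.0 + std::exp(-a[k]));
    s[k] = sk;
    y[k] = a[k] * sk;
  }
  return List::create(_["y"] = y, _["s"] = s);
}
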