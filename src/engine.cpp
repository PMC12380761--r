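// Numerical core of the network engine.
//
// Feature maps are R arrays with dim = c(H, W, C, N) (column-major, so one
// channel plane of one sample is contiguous).  Convolution weights have
// dim = c(kh, kw, Cin/groups, Cout); the flattened kernel index order
// (kh fastest, then kw, then channel) matches the im2col column order below.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void im2col_group(const double* xp, int H, int W, int c0, int cing,
                                int kh, int kw, int stride, int pad,
                                int Ho, int Wo, arma::mat& A) {
  // xp: start of one sample's block (H*W*C doubles); fills A (Ho*Wo x kh*kw*cing)
  for (int ci = 0; ci < cing; ++ci) {
    const double* plane = xp + (size_t)(c0 + ci) * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int k = khi + kh * (kwi + kw * ci);
        double* acol = A.colptr(k);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kwi;
          double* adst = acol + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) { std::fill(adst, adst + Ho, 0.0); continue; }
          const double* pcol = plane + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + khi;
            adst[ho] = (hi >= 0 && hi < H) ? pcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_group(double* gxp, int H, int W, int c0, int cing,
                                int kh, int kw, int stride, int pad,
                                int Ho, int Wo, const arma::mat& Gc) {
  for (int ci = 0; ci < cing; ++ci) {
    double* plane = gxp + (size_t)(c0 + ci) * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int k = khi + kh * (kwi + kw * ci);
        const double* gcol = Gc.colptr(k);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kwi;
          if (wi < 0 || wi >= W) continue;
          double* pcol = plane + (size_t)wi * H;
          const double* gsrc = gcol + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + khi;
            if (hi >= 0 && hi < H) pcol[hi] += gsrc[ho];
          }
        }
      }
    }
  }
}

// Direct depthwise convolution (groups == C, one input channel per output).
static void dwconv_fwd(const double* xp, const double* wp, double* yp,
                       int H, int W, int C, int N, int kh, int kw,
                       int stride, int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((size_t)n * C + c) * H * W;
      const double* ker = wp + (size_t)c * kh * kw;
      double* out = yp + ((size_t)n * C + c) * Ho * Wo;
      std::fill(out, out + (size_t)Ho * Wo, 0.0);
      for (int kwi = 0; kwi < kw; ++kwi) {
        for (int khi = 0; khi < kh; ++khi) {
          double wv = ker[khi + kh * kwi];
          if (wv == 0.0) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kwi;
            if (wi < 0 || wi >= W) continue;
            const double* pc = plane + (size_t)wi * H;
            double* oc = out + (size_t)wo * Ho;
            int ho0 = std::max(0, (pad - khi + stride - 1) / stride);
            for (int ho = ho0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + khi;
              if (hi >= H) break;
              oc[ho] += wv * pc[hi];
            }
          }
        }
      }
    }
  }
}

static void dwconv_bwd(const double* xp, const double* wp, const double* gyp,
                       double* gxp, double* gwp, int H, int W, int C, int N,
                       int kh, int kw, int stride, int pad, int Ho, int Wo,
                       bool need_gx) {
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((size_t)n * C + c) * H * W;
      const double* ker = wp + (size_t)c * kh * kw;
      const double* gout = gyp + ((size_t)n * C + c) * Ho * Wo;
      double* gplane = need_gx ? gxp + ((size_t)n * C + c) * H * W : nullptr;
      double* gker = gwp + (size_t)c * kh * kw;
      for (int kwi = 0; kwi < kw; ++kwi) {
        for (int khi = 0; khi < kh; ++khi) {
          double wv = ker[khi + kh * kwi];
          double acc = 0.0;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kwi;
            if (wi < 0 || wi >= W) continue;
            const double* pc = plane + (size_t)wi * H;
            double* gc = need_gx ? gplane + (size_t)wi * H : nullptr;
            const double* go = gout + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + khi;
              if (hi < 0 || hi >= H) continue;
              acc += go[ho] * pc[hi];
              if (need_gx) gc[hi] += wv * go[ho];
            }
          }
          gker[khi + kh * kwi] += acc;
        }
      }
    }
  }
}

// Direct convolution for small per-group channel counts: loops over taps
// and channels with contiguous inner columns (vectorizable), no im2col.
static void direct_fwd(const double* xp0, const double* wp, double* yp0,
                       int H, int W, int C, int N, int kh, int kw,
                       int cing, int cout, int groups, int stride, int pad,
                       int Ho, int Wo) {
  const int coutg = cout / groups;
  for (int n = 0; n < N; ++n) {
    const double* xs = xp0 + (size_t)n * H * W * C;
    double* ys = yp0 + (size_t)n * Ho * Wo * cout;
    for (int g = 0; g < groups; ++g) {
      for (int co = 0; co < coutg; ++co) {
        double* out = ys + (size_t)(g * coutg + co) * Ho * Wo;
        std::fill(out, out + (size_t)Ho * Wo, 0.0);
        const double* ker0 = wp + (size_t)(g * coutg + co) * kh * kw * cing;
        for (int ci = 0; ci < cing; ++ci) {
          const double* plane = xs + (size_t)(g * cing + ci) * H * W;
          const double* ker = ker0 + (size_t)ci * kh * kw;
          for (int kwi = 0; kwi < kw; ++kwi) {
            for (int khi = 0; khi < kh; ++khi) {
              double wv = ker[khi + kh * kwi];
              for (int wo = 0; wo < Wo; ++wo) {
                int wi = wo * stride - pad + kwi;
                if (wi < 0 || wi >= W) continue;
                const double* pc = plane + (size_t)wi * H;
                double* oc = out + (size_t)wo * Ho;
                if (stride == 1) {
                  int h0 = std::max(0, pad - khi);
                  int h1 = std::min(Ho, H + pad - khi);
                  const double* ps = pc - pad + khi;
                  for (int ho = h0; ho < h1; ++ho) oc[ho] += wv * ps[ho];
                } else {
                  for (int ho = 0; ho < Ho; ++ho) {
                    int hi = ho * stride - pad + khi;
                    if (hi >= 0 && hi < H) oc[ho] += wv * pc[hi];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}

static void direct_bwd(const double* xp0, const double* wp, const double* gyp0,
                       double* gxp0, double* gwp,
                       int H, int W, int C, int N, int kh, int kw,
                       int cing, int cout, int groups, int stride, int pad,
                       int Ho, int Wo, bool need_gx) {
  const int coutg = cout / groups;
  for (int n = 0; n < N; ++n) {
    const double* xs = xp0 + (size_t)n * H * W * C;
    const double* gys = gyp0 + (size_t)n * Ho * Wo * cout;
    double* gxs = need_gx ? gxp0 + (size_t)n * H * W * C : nullptr;
    for (int g = 0; g < groups; ++g) {
      for (int co = 0; co < coutg; ++co) {
        const double* gout = gys + (size_t)(g * coutg + co) * Ho * Wo;
        const double* ker0 = wp + (size_t)(g * coutg + co) * kh * kw * cing;
        double* gker0 = gwp + (size_t)(g * coutg + co) * kh * kw * cing;
        for (int ci = 0; ci < cing; ++ci) {
          const double* plane = xs + (size_t)(g * cing + ci) * H * W;
          double* gplane = need_gx ? gxs + (size_t)(g * cing + ci) * H * W : nullptr;
          const double* ker = ker0 + (size_t)ci * kh * kw;
          double* gker = gker0 + (size_t)ci * kh * kw;
          for (int kwi = 0; kwi < kw; ++kwi) {
            for (int khi = 0; khi < kh; ++khi) {
              double wv = ker[khi + kh * kwi];
              double acc = 0.0;
              for (int wo = 0; wo < Wo; ++wo) {
                int wi = wo * stride - pad + kwi;
                if (wi < 0 || wi >= W) continue;
                const double* pc = plane + (size_t)wi * H;
                double* gc = need_gx ? gplane + (size_t)wi * H : nullptr;
                const double* go = gout + (size_t)wo * Ho;
                if (stride == 1) {
                  int h0 = std::max(0, pad - khi);
                  int h1 = std::min(Ho, H + pad - khi);
                  const double* ps = pc - pad + khi;
                  double* gs = need_gx ? gc - pad + khi : nullptr;
                  for (int ho = h0; ho < h1; ++ho) acc += go[ho] * ps[ho];
                  if (need_gx)
                    for (int ho = h0; ho < h1; ++ho) gs[ho] += wv * go[ho];
                } else {
                  for (int ho = 0; ho < Ho; ++ho) {
                    int hi = ho * stride - pad + khi;
                    if (hi < 0 || hi >= H) continue;
                    acc += go[ho] * pc[hi];
                    if (need_gx) gc[hi] += wv * go[ho];
                  }
                }
              }
              gker[khi + kh * kwi] += acc;
            }
          }
        }
      }
    }
  }
}

#define DIRECT_CONV_CING_MAX 8

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");  // H W C N
  IntegerVector wd = w.attr("dim");  // kh kw cing cout
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  if (cing * groups != C) stop("conv2d: input channels %d incompatible with kernel %d x groups %d", C, cing, groups);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int coutg = cout / groups;
  const int K = kh * kw * cing;
  NumericVector y((R_xlen_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const double* xp0 = x.begin();
  double* yp0 = y.begin();
  const double* wp = w.begin();
  NumericVector bvec;
  const double* bp = nullptr;
  if (bias.isNotNull()) { bvec = NumericVector(bias); bp = bvec.begin(); }
  if (kh == 1 && kw == 1 && groups == 1 && stride == 1) {
    // pointwise: one gemm per sample, no im2col
    arma::mat Wm(const_cast<double*>(wp), C, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(xp0) + (size_t)n * H * W * C,
                  (size_t)H * W, C, false, true);
      arma::mat Y(yp0 + (size_t)n * H * W * cout, (size_t)H * W, cout, false, true);
      Y = X * Wm;
    }
  } else if (groups == C && cing == 1 && cout == C) {
    dwconv_fwd(xp0, wp, yp0, H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  } else if (cing <= DIRECT_CONV_CING_MAX) {
    direct_fwd(xp0, wp, yp0, H, W, C, N, kh, kw, cing, cout, groups,
               stride, pad, Ho, Wo);
  } else {
    // sample-batched im2col: one gemm per group over all N samples
    const size_t hwo = (size_t)Ho * Wo;
    arma::mat A((size_t)N * hwo, K);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        // fill rows [n*hwo, (n+1)*hwo) of A
        for (int ci = 0; ci < cing; ++ci) {
          const double* plane = xp0 + (size_t)n * H * W * C +
            (size_t)(g * cing + ci) * H * W;
          for (int kwi = 0; kwi < kw; ++kwi) {
            for (int khi = 0; khi < kh; ++khi) {
              int k2 = khi + kh * (kwi + kw * ci);
              double* acol = A.colptr(k2) + (size_t)n * hwo;
              for (int wo = 0; wo < Wo; ++wo) {
                int wi = wo * stride - pad + kwi;
                double* adst = acol + (size_t)wo * Ho;
                if (wi < 0 || wi >= W) { std::fill(adst, adst + Ho, 0.0); continue; }
                const double* pcol = plane + (size_t)wi * H;
                for (int ho = 0; ho < Ho; ++ho) {
                  int hi = ho * stride - pad + khi;
                  adst[ho] = (hi >= 0 && hi < H) ? pcol[hi] : 0.0;
                }
              }
            }
          }
        }
      }
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * coutg * g, K, coutg, false, true);
      arma::mat Yall = A * Wg;   // (N*hwo) x coutg
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < coutg; ++c)
          std::copy(Yall.colptr(c) + (size_t)n * hwo,
                    Yall.colptr(c) + (size_t)(n + 1) * hwo,
                    yp0 + (size_t)n * hwo * cout + (size_t)(g * coutg + c) * hwo);
    }
  }
  if (bp) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        double* pc = yp0 + ((size_t)n * cout + c) * Ho * Wo;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) pc[i] += bp[c];
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int groups, bool need_gx,
                    bool need_gb = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int coutg = cout / groups;
  const int K = kh * kw * cing;
  NumericVector gw((R_xlen_t)kh * kw * cing * cout);
  gw.attr("dim") = wd;
  NumericVector gb(cout);
  NumericVector gx;
  double* gxp0 = nullptr;
  if (need_gx) {
    gx = NumericVector((R_xlen_t)H * W * C * N);
    gx.attr("dim") = xd;
    gxp0 = gx.begin();
  }
  const double* xp0 = x.begin();
  const double* wp = w.begin();
  const double* gyp0 = gy.begin();
  double* gwp = gw.begin();
  double* gbp = gb.begin();
  if (need_gb)
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const double* pc = gyp0 + ((size_t)n * cout + c) * Ho * Wo;
        double acc = 0.0;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) acc += pc[i];
        gbp[c] += acc;
      }
  if (kh == 1 && kw == 1 && groups == 1 && stride == 1) {
    arma::mat Wm(const_cast<double*>(wp), C, cout, false, true);
    arma::mat Gwm(gwp, C, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(xp0) + (size_t)n * H * W * C,
                  (size_t)H * W, C, false, true);
      arma::mat Gy(const_cast<double*>(gyp0) + (size_t)n * H * W * cout,
                   (size_t)H * W, cout, false, true);
      Gwm += X.t() * Gy;
      if (need_gx) {
        arma::mat Gx(gxp0 + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
        Gx = Gy * Wm.t();
      }
    }
  } else if (groups == C && cing == 1 && cout == C) {
    dwconv_bwd(xp0, wp, gyp0, gxp0, gwp, H, W, C, N, kh, kw, stride, pad,
               Ho, Wo, need_gx);
  } else if (cing <= DIRECT_CONV_CING_MAX) {
    direct_bwd(xp0, wp, gyp0, gxp0, gwp, H, W, C, N, kh, kw, cing, cout,
               groups, stride, pad, Ho, Wo, need_gx);
  } else {
    const size_t hwo = (size_t)Ho * Wo;
    arma::mat A((size_t)N * hwo, K), Gy((size_t)N * hwo, coutg);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        for (int ci = 0; ci < cing; ++ci) {
          const double* plane = xp0 + (size_t)n * H * W * C +
            (size_t)(g * cing + ci) * H * W;
          for (int kwi = 0; kwi < kw; ++kwi) {
            for (int khi = 0; khi < kh; ++khi) {
              int k2 = khi + kh * (kwi + kw * ci);
              double* acol = A.colptr(k2) + (size_t)n * hwo;
              for (int wo = 0; wo < Wo; ++wo) {
                int wi = wo * stride - pad + kwi;
                double* adst = acol + (size_t)wo * Ho;
                if (wi < 0 || wi >= W) { std::fill(adst, adst + Ho, 0.0); continue; }
                const double* pcol = plane + (size_t)wi * H;
                for (int ho = 0; ho < Ho; ++ho) {
                  int hi = ho * stride - pad + khi;
                  adst[ho] = (hi >= 0 && hi < H) ? pcol[hi] : 0.0;
                }
              }
            }
          }
        }
        for (int c = 0; c < coutg; ++c)
          std::copy(gyp0 + (size_t)n * hwo * cout + (size_t)(g * coutg + c) * hwo,
                    gyp0 + (size_t)n * hwo * cout + (size_t)(g * coutg + c + 1) * hwo,
                    Gy.colptr(c) + (size_t)n * hwo);
      }
      arma::mat Gw(gwp + (size_t)K * coutg * g, K, coutg, false, true);
      Gw += A.t() * Gy;
      if (need_gx) {
        arma::mat Wg(const_cast<double*>(wp) + (size_t)K * coutg * g, K, coutg, false, true);
        arma::mat Gc = Gy * Wg.t();   // (N*hwo) x K
        for (int n = 0; n < N; ++n) {
          arma::mat Gcn = Gc.rows((size_t)n * hwo, (size_t)(n + 1) * hwo - 1);
          col2im_group(gxp0 + (size_t)n * H * W * C, H, W, g * cing, cing,
                       kh, kw, stride, pad, Ho, Wo, Gcn);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Fused batch-norm + activation, forward and backward, elementwise in C++.
// act: 0 none, 1 SiLU, 2 ReLU, 3 sigmoid.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bnact_fwd(NumericVector xc, NumericVector gamma, NumericVector beta,
                   NumericVector rmean_in, NumericVector rvar_in, bool training,
                   double momentum, double eps, int act) {
  IntegerVector d = xc.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector rmean = clone(rmean_in), rvar = clone(rvar_in);
  NumericVector y((R_xlen_t)hw * C * N);
  y.attr("dim") = d;
  NumericVector mu(C), inv(C);
  const double* xp = xc.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* pc = xp + ((size_t)n * C + c) * hw;
        for (size_t i = 0; i < hw; ++i) { s += pc[i]; s2 += pc[i] * pc[i]; }
      }
      double M = (double)hw * N;
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      rmean[c] = (1 - momentum) * rmean[c] + momentum * m;
      rvar[c] = (1 - momentum) * rvar[c] + momentum * v;
    } else {
      m = rmean[c]; v = rvar[c];
    }
    mu[c] = m;
    inv[c] = 1.0 / std::sqrt(v + eps);
    double sc = gamma[c] * inv[c];
    double sh = beta[c] - sc * m;
    for (int n = 0; n < N; ++n) {
      const double* pc = xp + ((size_t)n * C + c) * hw;
      double* py = yp + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        double z = pc[i] * sc + sh;
        switch (act) {
          case 1: py[i] = z / (1.0 + std::exp(-z)); break;
          case 2: py[i] = z > 0 ? z : 0.0; break;
          case 3: py[i] = 1.0 / (1.0 + std::exp(-z)); break;
          default: py[i] = z;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv,
                      _["rmean"] = rmean, _["rvar"] = rvar);
}

// [[Rcpp::export]]
List cpp_bnact_bwd(NumericVector xc, NumericVector gy, NumericVector gamma,
                   NumericVector beta, NumericVector mu, NumericVector inv,
                   int act) {
  IntegerVector d = xc.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector gxc((R_xlen_t)hw * C * N);
  gxc.attr("dim") = d;
  NumericVector ggamma(C), gbeta(C);
  const double* xp = xc.begin();
  const double* gp = gy.begin();
  double* gxp = gxc.begin();
  const double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double sc = gamma[c] * inv[c];
    double sh = beta[c] - sc * mu[c];
    double sum_gz = 0, sum_gzx = 0;
    // first pass: gz (stored in gxc temporarily) and reductions
    for (int n = 0; n < N; ++n) {
      const double* pc = xp + ((size_t)n * C + c) * hw;
      const double* pg = gp + ((size_t)n * C + c) * hw;
      double* pgx = gxp + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        double z = pc[i] * sc + sh;
        double gz;
        switch (act) {
          case 1: {
            double s = 1.0 / (1.0 + std::exp(-z));
            gz = pg[i] * s * (1.0 + z * (1.0 - s));
            break;
          }
          case 2: gz = z > 0 ? pg[i] : 0.0; break;
          case 3: {
            double s = 1.0 / (1.0 + std::exp(-z));
            gz = pg[i] * s * (1.0 - s);
            break;
          }
          default: gz = pg[i];
        }
        pgx[i] = gz;
        double xhat = (pc[i] - mu[c]) * inv[c];
        sum_gz += gz;
        sum_gzx += gz * xhat;
      }
    }
    gbeta[c] = sum_gz;
    ggamma[c] = sum_gzx;
    // second pass: gxc = sc * (gz - sum_gz/M - xhat * sum_gzx/M)
    double t1 = sum_gz / M, t2 = sum_gzx / M;
    for (int n = 0; n < N; ++n) {
      const double* pc = xp + ((size_t)n * C + c) * hw;
      double* pgx = gxp + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        double xhat = (pc[i] - mu[c]) * inv[c];
        pgx[i] = sc * (pgx[i] - t1 - xhat * t2);
      }
    }
  }
  return List::create(_["gxc"] = gxc, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Plain elementwise activation forward/backward (for convs without BN).
// [[Rcpp::export]]
NumericVector cpp_act_fwd(NumericVector z, int act) {
  NumericVector y(z.size());
  y.attr("dim") = z.attr("dim");
  const double* zp = z.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    double v = zp[i];
    switch (act) {
      case 1: yp[i] = v / (1.0 + std::exp(-v)); break;
      case 2: yp[i] = v > 0 ? v : 0.0; break;
      case 3: yp[i] = 1.0 / (1.0 + std::exp(-v)); break;
      default: yp[i] = v;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_act_bwd(NumericVector z, NumericVector gy, int act) {
  NumericVector g(z.size());
  g.attr("dim") = z.attr("dim");
  const double* zp = z.begin();
  const double* gp = gy.begin();
  double* out = g.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    double v = zp[i];
    switch (act) {
      case 1: {
        double s = 1.0 / (1.0 + std::exp(-v));
        out[i] = gp[i] * s * (1.0 + v * (1.0 - s));
        break;
      }
      case 2: out[i] = v > 0 ? gp[i] : 0.0; break;
      case 3: {
        double s = 1.0 / (1.0 + std::exp(-v));
        out[i] = gp[i] * s * (1.0 - s);
        break;
      }
      default: out[i] = gp[i];
    }
  }
  return g;
}

// Max pooling, stride 1, symmetric padding (used by the SPPF context block).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = xd;
  IntegerVector arg((R_xlen_t)H * W * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = INTEGER(arg);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* px = xp + p * H * W;
    double* py = yp + p * H * W;
    int* pa = ap + p * H * W;
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        double best = -INFINITY; int bidx = -1;
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho - pad + dh;
            if (hi < 0 || hi >= H) continue;
            double v = px[hi + (size_t)wi * H];
            if (v > best) { best = v; bidx = hi + wi * H; }
          }
        }
        py[ho + (size_t)wo * H] = best;
        pa[ho + (size_t)wo * H] = bidx;
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector arg) {
  IntegerVector yd = gy.attr("dim");
  const int H = yd[0], W = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = yd;
  const double* gp = gy.begin();
  const int* ap = INTEGER(arg);
  double* xp = gx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* pg = gp + p * H * W;
    const int* pa = ap + p * H * W;
    double* px = xp + p * H * W;
    for (size_t i = 0; i < (size_t)H * W; ++i) px[pa[i]] += pg[i];
  }
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_up2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* px = xp + p * H * W;
    double* py = yp + p * 4 * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double v = px[h + (size_t)w * H];
        size_t base = (size_t)2 * h + (size_t)2 * w * 2 * H;
        py[base] = v; py[base + 1] = v;
        py[base + 2 * H] = v; py[base + 2 * H + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* pg = gp + p * (size_t)H2 * W2;
    double* px = xp + p * (size_t)H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        size_t base = (size_t)2 * h + (size_t)2 * w * H2;
        px[h + (size_t)w * H] =
          pg[base] + pg[base + 1] + pg[base + H2] + pg[base + H2 + 1];
      }
    }
  }
  return gx;
}

// Per-pixel mean and max across channels -> (H, W, 2, N) map.
// [[Rcpp::export]]
List cpp_chanpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)H * W * 2 * N);
  y.attr("dim") = IntegerVector::create(H, W, 2, N);
  IntegerVector arg((R_xlen_t)H * W * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = INTEGER(arg);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* px = xp + (size_t)n * hw * C;
    double* pm = yp + (size_t)n * hw * 2;        // mean plane
    double* pM = pm + hw;                        // max plane
    int* pa = ap + (size_t)n * hw;
    for (size_t i = 0; i < hw; ++i) { pm[i] = 0.0; pM[i] = -INFINITY; pa[i] = 0; }
    for (int c = 0; c < C; ++c) {
      const double* plane = px + (size_t)c * hw;
      for (size_t i = 0; i < hw; ++i) {
        pm[i] += plane[i];
        if (plane[i] > pM[i]) { pM[i] = plane[i]; pa[i] = c; }
      }
    }
    for (size_t i = 0; i < hw; ++i) pm[i] /= C;
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_chanpool_bwd(NumericVector gy, IntegerVector arg, int C) {
  IntegerVector yd = gy.attr("dim");
  const int H = yd[0], W = yd[1], N = yd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gy.begin();
  const int* ap = INTEGER(arg);
  double* xp = gx.begin();
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* gm = gp + (size_t)n * hw * 2;
    const double* gM = gm + hw;
    const int* pa = ap + (size_t)n * hw;
    double* px = xp + (size_t)n * hw * C;
    for (int c = 0; c < C; ++c) {
      double* plane = px + (size_t)c * hw;
      for (size_t i = 0; i < hw; ++i) plane[i] = gm[i] / C;
    }
    for (size_t i = 0; i < hw; ++i) px[(size_t)pa[i] * hw + i] += gM[i];
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Distribution-head helpers: softmax over bins for each of 4 box sides,
// applied to a whole level map (H, W, 4*reg_max, N).  Returns bin
// probabilities (same shape) and expected bin index (H, W, 4, N).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_dfl_softmax(NumericVector x, int reg_max) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector prob((R_xlen_t)hw * C * N);
  prob.attr("dim") = d;
  NumericVector dist((R_xlen_t)hw * 4 * N);
  dist.attr("dim") = IntegerVector::create(H, W, 4, N);
  const double* xp = x.begin();
  double* pp = prob.begin();
  double* dp = dist.begin();
  std::vector<double> e(reg_max);
  for (int n = 0; n < N; ++n) {
    for (int sd = 0; sd < 4; ++sd) {
      const double* xin = xp + ((size_t)n * C + sd * reg_max) * hw;
      double* pout = pp + ((size_t)n * C + sd * reg_max) * hw;
      double* dout = dp + ((size_t)n * 4 + sd) * hw;
      for (size_t i = 0; i < hw; ++i) {
        double mx = xin[i];
        for (int b = 1; b < reg_max; ++b)
          mx = std::max(mx, xin[i + (size_t)b * hw]);
        double s = 0;
        for (int b = 0; b < reg_max; ++b) {
          e[b] = std::exp(xin[i + (size_t)b * hw] - mx);
          s += e[b];
        }
        double ex = 0;
        for (int b = 0; b < reg_max; ++b) {
          double p = e[b] / s;
          pout[i + (size_t)b * hw] = p;
          ex += p * b;
        }
        dout[i] = ex;
      }
    }
  }
  return List::create(_["prob"] = prob, _["dist"] = dist);
}

// Elementwise sigmoid over a whole array.
// [[Rcpp::export]]
NumericVector cpp_sigmoid(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return y;
}

// Space-to-depth rearrangement (scale s): (H,W,C,N) -> (H/s, W/s, s*s*C, N),
// channel blocks ordered row-major over the (dh, dw) offsets.
// [[Rcpp::export]]
NumericVector cpp_spd_fwd(NumericVector x, int s) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / s, Wo = W / s;
  NumericVector y((R_xlen_t)Ho * Wo * s * s * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, s * s * C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int dh = 0; dh < s; ++dh) for (int dw = 0; dw < s; ++dw) {
      int blk = dh * s + dw;
      for (int c = 0; c < C; ++c) {
        const double* src = xp + ((size_t)n * C + c) * H * W;
        double* dst = yp + ((size_t)n * s * s * C + blk * C + c) * Ho * Wo;
        for (int wo = 0; wo < Wo; ++wo) {
          const double* sc = src + ((size_t)wo * s + dw) * H + dh;
          double* dc = dst + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) dc[ho] = sc[(size_t)ho * s];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_spd_bwd(NumericVector gy, int s) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C2 = d[2], N = d[3];
  const int C = C2 / (s * s), H = Ho * s, W = Wo * s;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int dh = 0; dh < s; ++dh) for (int dw = 0; dw < s; ++dw) {
      int blk = dh * s + dw;
      for (int c = 0; c < C; ++c) {
        double* dst = xp + ((size_t)n * C + c) * H * W;
        const double* src = gp + ((size_t)n * C2 + blk * C + c) * Ho * Wo;
        for (int wo = 0; wo < Wo; ++wo) {
          double* dc = dst + ((size_t)wo * s + dw) * H + dh;
          const double* sc = src + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) dc[(size_t)ho * s] = sc[ho];
        }
      }
    }
  }
  return gx;
}

// Channel-wise concatenation of a list of (H,W,Ci,N) arrays.
// [[Rcpp::export]]
NumericVector cpp_concat(List xs) {
  int K = xs.size();
  std::vector<NumericVector> v(K);
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> Cs(K);
  for (int k = 0; k < K; ++k) {
    v[k] = as<NumericVector>(xs[k]);
    IntegerVector d = v[k].attr("dim");
    if (k == 0) { H = d[0]; W = d[1]; N = d[3]; }
    Cs[k] = d[2];
    Ctot += d[2];
  }
  NumericVector y((R_xlen_t)H * W * Ctot * N);
  y.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  double* yp = y.begin();
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    size_t at = 0;
    for (int k = 0; k < K; ++k) {
      const double* xp = v[k].begin() + (size_t)n * Cs[k] * hw;
      std::copy(xp, xp + (size_t)Cs[k] * hw,
                yp + ((size_t)n * Ctot + at) * hw);
      at += Cs[k];
    }
  }
  return y;
}

// Channel slice [from, to] (1-based inclusive).
// [[Rcpp::export]]
NumericVector cpp_chslice(NumericVector x, int from, int to) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cs = to - from + 1;
  NumericVector y((R_xlen_t)H * W * Cs * N);
  y.attr("dim") = IntegerVector::create(H, W, Cs, N);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + ((size_t)n * C + from - 1) * hw,
              x.begin() + ((size_t)n * C + to) * hw,
              y.begin() + (size_t)n * Cs * hw);
  return y;
}

// Scatter a channel-slice gradient back into a zero tensor of C channels.
// [[Rcpp::export]]
NumericVector cpp_chslice_bwd(NumericVector gy, int from, int C) {
  IntegerVector d = gy.attr("dim");
  const int H = d[0], W = d[1], Cs = d[2], N = d[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    std::copy(gy.begin() + (size_t)n * Cs * hw,
              gy.begin() + (size_t)(n + 1) * Cs * hw,
              gx.begin() + ((size_t)n * C + from - 1) * hw);
  return gx;
}

// n-ary elementwise sum.
// [[Rcpp::export]]
NumericVector cpp_addn(List xs) {
  NumericVector x0 = as<NumericVector>(xs[0]);
  NumericVector y = clone(x0);
  for (int k = 1; k < xs.size(); ++k) {
    NumericVector xk = as<NumericVector>(xs[k]);
    double* yp = y.begin();
    const double* xp = xk.begin();
    for (R_xlen_t i = 0; i < y.size(); ++i) yp[i] += xp[i];
  }
  return y;
}
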