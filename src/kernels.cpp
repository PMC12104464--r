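// Compiled kernels for the training engine.
//
// Tensor layout everywhere: dim = c(C, H, W, B), channel fastest. The 3x3
// convolution is evaluated as im2col + GEMM; its backward pass reuses the
// gathered column matrix. Loops are written against raw pointers; GEMMs go
// through Armadillo (BLAS).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- 3x3 convolution, pad 1, stride 1 --------------------------------------

// gathers 3x3 neighbourhoods: COL is K x (N*B), K = Cin*9 with
// k = cin + Cin*(kh + 3*kw), column n + N*b with n = h + H*w
static void im2col3(const double* x, int Cin, int H, int W, int B,
                    arma::mat& COL) {
  const int N = H * W;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)Cin * N * b;
    for (int w_ = 0; w_ < W; ++w_) {
      for (int h = 0; h < H; ++h) {
        double* col = COL.colptr((size_t)(h + H * w_) + (size_t)N * b);
        for (int kw = 0; kw < 3; ++kw) {
          int ws = w_ + kw - 1;
          for (int kh = 0; kh < 3; ++kh) {
            int hs = h + kh - 1;
            double* dst = col + (size_t)Cin * (kh + 3 * kw);
            if (hs >= 0 && hs < H && ws >= 0 && ws < W) {
              const double* src = xb + (size_t)Cin * (hs + H * ws);
              std::copy(src, src + Cin, dst);
            } else {
              std::fill(dst, dst + Cin, 0.0);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv3_fwd(NumericVector x, NumericMatrix w,
                   int Cin, int H, int W, int B) {
  const int K = Cin * 9, N = H * W;
  const int Cout = w.nrow();
  arma::mat COL(K, (size_t)N * B);
  im2col3(x.begin(), Cin, H, W, B, COL);
  arma::mat Wm(w.begin(), Cout, K, false, true);
  arma::mat OUT = Wm * COL;
  NumericVector out(OUT.begin(), OUT.end());
  out.attr("dim") = IntegerVector::create(Cout, H, W, B);
  return List::create(_["out"] = out,
                      _["col"] = XPtr<arma::mat>(new arma::mat(std::move(COL))));
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector g, NumericMatrix w, SEXP colPtr,
                   int Cin, int H, int W, int B) {
  const int K = Cin * 9, N = H * W;
  const int Cout = w.nrow();
  XPtr<arma::mat> COL(colPtr);
  arma::mat Gm(g.begin(), Cout, (size_t)N * B, false, true);
  arma::mat dW = Gm * COL->t();
  arma::mat Wm(w.begin(), Cout, K, false, true);
  arma::mat dCOL = Wm.t() * Gm;              // K x (N*B)
  NumericVector dx((size_t)Cin * N * B);
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    double* dxb = dxp + (size_t)Cin * N * b;
    for (int w_ = 0; w_ < W; ++w_) {
      for (int h = 0; h < H; ++h) {
        const double* col = dCOL.colptr((size_t)(h + H * w_) + (size_t)N * b);
        for (int kw = 0; kw < 3; ++kw) {
          int ws = w_ + kw - 1;
          if (ws < 0 || ws >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            int hs = h + kh - 1;
            if (hs < 0 || hs >= H) continue;
            const double* src = col + (size_t)Cin * (kh + 3 * kw);
            double* dst = dxb + (size_t)Cin * (hs + H * ws);
            for (int c = 0; c < Cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(Cin, H, W, B);
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW));
}

// ---- transposed conv 2x2, stride 2 ------------------------------------------
// w rows indexed (cout, dh, dw), cout fastest; each input pixel paints one
// 2x2 output block.

// [[Rcpp::export]]
NumericVector cpp_convT2_fwd(NumericVector x, NumericMatrix w,
                             NumericVector bias,
                             int Cin, int H, int W, int B) {
  const int N = H * W;
  const int Cout = w.nrow() / 4;
  arma::mat Xm(x.begin(), Cin, (size_t)N * B, false, true);
  arma::mat Wm(w.begin(), Cout * 4, Cin, false, true);
  arma::mat M = Wm * Xm;                     // (Cout*4) x (N*B)
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Cout * Ho * Wo * B);
  double* op = out.begin();
  const double* bp = bias.begin();
  for (int b = 0; b < B; ++b) {
    double* ob = op + (size_t)Cout * Ho * Wo * b;
    for (int w_ = 0; w_ < W; ++w_) {
      for (int h = 0; h < H; ++h) {
        const double* m = M.colptr((size_t)(h + H * w_) + (size_t)N * b);
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            double* dst = ob + (size_t)Cout *
              ((2 * h + dh) + (size_t)Ho * (2 * w_ + dw));
            const double* src = m + (size_t)Cout * (dh + 2 * dw);
            for (int c = 0; c < Cout; ++c) dst[c] = src[c] + bp[c];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, B);
  return out;
}

// [[Rcpp::export]]
List cpp_convT2_bwd(NumericVector g, NumericVector x, NumericMatrix w,
                    int Cin, int H, int W, int B) {
  const int N = H * W;
  const int Cout = w.nrow() / 4;
  const int Ho = 2 * H, Wo = 2 * W;
  // regroup gradient into (Cout*4) x (N*B)
  arma::mat Gm(Cout * 4, (size_t)N * B);
  NumericVector db(Cout);
  const double* gp = g.begin();
  for (int b = 0; b < B; ++b) {
    const double* gb = gp + (size_t)Cout * Ho * Wo * b;
    for (int w_ = 0; w_ < W; ++w_) {
      for (int h = 0; h < H; ++h) {
        double* m = Gm.colptr((size_t)(h + H * w_) + (size_t)N * b);
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const double* src = gb + (size_t)Cout *
              ((2 * h + dh) + (size_t)Ho * (2 * w_ + dw));
            double* dst = m + (size_t)Cout * (dh + 2 * dw);
            for (int c = 0; c < Cout; ++c) { dst[c] = src[c]; db[c] += src[c]; }
          }
        }
      }
    }
  }
  arma::mat Xm(x.begin(), Cin, (size_t)N * B, false, true);
  arma::mat Wm(w.begin(), Cout * 4, Cin, false, true);
  arma::mat dW = Gm * Xm.t();
  arma::mat dX = Wm.t() * Gm;                // Cin x (N*B)
  NumericVector dx(dX.begin(), dX.end());
  dx.attr("dim") = IntegerVector::create(Cin, H, W, B);
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = db);
}

// ---- 2x2 max pooling ---------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, int C, int H, int W, int B) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)C * Ho * Wo * B);
  IntegerVector which((size_t)C * Ho * Wo * B);
  const double* xp = x.begin();
  double* op = out.begin();
  int* wp = which.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (size_t)C * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t o = (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          double best = -INFINITY; int bj = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              double v = xb[c + (size_t)C *
                ((2 * ho + dh) + (size_t)H * (2 * wo + dw))];
              int j = dh + 2 * dw;
              if (v > best) { best = v; bj = j; }
            }
          }
          op[o + c] = best;
          wp[o + c] = bj;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector g, IntegerVector which,
                               int C, int H, int W, int B) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)C * H * W * B);
  double* dxp = dx.begin();
  const double* gp = g.begin();
  const int* wp = which.begin();
  for (int b = 0; b < B; ++b) {
    double* dxb = dxp + (size_t)C * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t o = (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          int j = wp[o + c];
          int dh = j % 2, dw = j / 2;
          dxb[c + (size_t)C * ((2 * ho + dh) + (size_t)H * (2 * wo + dw))] +=
            gp[o + c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  return dx;
}

// ---- bilinear x2 upsampling (align_corners = FALSE) -------------------------

static inline void lin_w2(int n_in, int o, int& lo, int& hi, double& t) {
  double s = (o + 0.5) / 2.0 - 0.5;
  double f = std::floor(s);
  lo = (int)f; if (lo < 0) lo = 0; if (lo > n_in - 1) lo = n_in - 1;
  hi = lo + 1; if (hi > n_in - 1) hi = n_in - 1;
  t = s - std::floor(s);
  if (s < 0) t = 0.0;
  if (s > n_in - 1) t = 1.0;
}

// [[Rcpp::export]]
NumericVector cpp_up2_fwd(NumericVector x, int C, int H, int W, int B) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)C * Ho * Wo * B);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (size_t)C * H * W * b;
    double* ob = op + (size_t)C * Ho * Wo * b;
    for (int wo = 0; wo < Wo; ++wo) {
      int wl, wh; double tw; lin_w2(W, wo, wl, wh, tw);
      for (int ho = 0; ho < Ho; ++ho) {
        int hl, hh; double th; lin_w2(H, ho, hl, hh, th);
        const double* s00 = xb + (size_t)C * (hl + (size_t)H * wl);
        const double* s10 = xb + (size_t)C * (hh + (size_t)H * wl);
        const double* s01 = xb + (size_t)C * (hl + (size_t)H * wh);
        const double* s11 = xb + (size_t)C * (hh + (size_t)H * wh);
        double w00 = (1 - th) * (1 - tw), w10 = th * (1 - tw);
        double w01 = (1 - th) * tw, w11 = th * tw;
        double* dst = ob + (size_t)C * (ho + (size_t)Ho * wo);
        for (int c = 0; c < C; ++c)
          dst[c] = w00 * s00[c] + w10 * s10[c] + w01 * s01[c] + w11 * s11[c];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bwd(NumericVector g, int C, int H, int W, int B) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)C * H * W * B);
  const double* gp = g.begin();
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    double* dxb = dxp + (size_t)C * H * W * b;
    const double* gb = gp + (size_t)C * Ho * Wo * b;
    for (int wo = 0; wo < Wo; ++wo) {
      int wl, wh; double tw; lin_w2(W, wo, wl, wh, tw);
      for (int ho = 0; ho < Ho; ++ho) {
        int hl, hh; double th; lin_w2(H, ho, hl, hh, th);
        double w00 = (1 - th) * (1 - tw), w10 = th * (1 - tw);
        double w01 = (1 - th) * tw, w11 = th * tw;
        const double* src = gb + (size_t)C * (ho + (size_t)Ho * wo);
        double* d00 = dxb + (size_t)C * (hl + (size_t)H * wl);
        double* d10 = dxb + (size_t)C * (hh + (size_t)H * wl);
        double* d01 = dxb + (size_t)C * (hl + (size_t)H * wh);
        double* d11 = dxb + (size_t)C * (hh + (size_t)H * wh);
        for (int c = 0; c < C; ++c) {
          d00[c] += w00 * src[c];
          d10[c] += w10 * src[c];
          d01[c] += w01 * src[c];
          d11[c] += w11 * src[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  return dx;
}

// ---- batch normalization -----------------------------------------------------

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mu, NumericVector var_, double eps,
                int C, int n) {
  NumericVector out((size_t)C * n), xhat((size_t)C * n), invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var_[c] + eps);
  const double* xp = x.begin();
  double* op = out.begin();
  double* hp = xhat.begin();
  for (int j = 0; j < n; ++j) {
    size_t o = (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      double h = (xp[o + c] - mu[c]) * invstd[c];
      hp[o + c] = h;
      op[o + c] = gamma[c] * h + beta[c];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector g, NumericVector xhat, NumericVector invstd,
                NumericVector gamma, bool training, int C, int n) {
  NumericVector dgamma(C), dbeta(C), dx((size_t)C * n);
  const double* gp = g.begin();
  const double* hp = xhat.begin();
  std::vector<double> sg(C, 0.0), sgh(C, 0.0);
  for (int j = 0; j < n; ++j) {
    size_t o = (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      double gv = gp[o + c];
      sg[c] += gv;
      sgh[c] += gv * hp[o + c];
    }
  }
  for (int c = 0; c < C; ++c) { dbeta[c] = sg[c]; dgamma[c] = sgh[c]; }
  double* dxp = dx.begin();
  if (training) {
    for (int j = 0; j < n; ++j) {
      size_t o = (size_t)C * j;
      for (int c = 0; c < C; ++c) {
        double dxh = gp[o + c] * gamma[c];
        dxp[o + c] = (invstd[c] / n) *
          (n * dxh - sg[c] * gamma[c] - hp[o + c] * sgh[c] * gamma[c]);
      }
    }
  } else {
    for (int j = 0; j < n; ++j) {
      size_t o = (size_t)C * j;
      for (int c = 0; c < C; ++c)
        dxp[o + c] = gp[o + c] * gamma[c] * invstd[c];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- channel stats (batch-norm forward statistics) ---------------------------

// [[Rcpp::export]]
List cpp_chan_stats(NumericVector x, int C, int n) {
  NumericVector mu(C), var_(C);
  const double* xp = x.begin();
  for (int j = 0; j < n; ++j) {
    size_t o = (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      double v = xp[o + c];
      mu[c] += v;
      var_[c] += v * v;
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= n;
    var_[c] = var_[c] / n - mu[c] * mu[c];
    if (var_[c] < 0) var_[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var_);
}

// ---- ReLU -------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector out(clone(x));
  double* p = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) if (p[i] < 0) p[i] = 0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector x) {
  NumericVector dx(clone(g));
  double* p = dx.begin();
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (xp[i] <= 0) p[i] = 0;
  return dx;
}

// ---- channel softmax ---------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_softmax_fwd(NumericVector x, int C, int n) {
  NumericVector out((size_t)C * n);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int j = 0; j < n; ++j) {
    size_t o = (size_t)C * j;
    double mx = xp[o];
    for (int c = 1; c < C; ++c) if (xp[o + c] > mx) mx = xp[o + c];
    double s = 0.0;
    for (int c = 0; c < C; ++c) { double e = std::exp(xp[o + c] - mx); op[o + c] = e; s += e; }
    for (int c = 0; c < C; ++c) op[o + c] /= s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_softmax_bwd(NumericVector g, NumericVector p, int C, int n) {
  NumericVector dx((size_t)C * n);
  const double* gp = g.begin();
  const double* pp = p.begin();
  double* dp = dx.begin();
  for (int j = 0; j < n; ++j) {
    size_t o = (size_t)C * j;
    double dot = 0.0;
    for (int c = 0; c < C; ++c) dot += gp[o + c] * pp[o + c];
    for (int c = 0; c < C; ++c) dp[o + c] = pp[o + c] * (gp[o + c] - dot);
  }
  return dx;
}

// ---- fused masked softmax cross-entropy --------------------------------------
// mean over masked pixels of -log softmax(O)[label]; backward is
// (softmax(O) - onehot(label)) * mask / n_masked

// [[Rcpp::export]]
List cpp_masked_ce_fwd(NumericVector O, IntegerVector label, LogicalVector mask,
                       int C, int n) {
  const double* op = O.begin();
  double acc = 0.0;
  int nm = 0;
  NumericVector P((size_t)C * n);
  double* pp = P.begin();
  for (int j = 0; j < n; ++j) {
    size_t o = (size_t)C * j;
    double mx = op[o];
    for (int c = 1; c < C; ++c) if (op[o + c] > mx) mx = op[o + c];
    double s = 0.0;
    for (int c = 0; c < C; ++c) { double e = std::exp(op[o + c] - mx); pp[o + c] = e; s += e; }
    for (int c = 0; c < C; ++c) pp[o + c] /= s;
    if (mask[j]) {
      double pl = pp[o + label[j]];
      if (pl < 1e-12) pl = 1e-12;
      acc -= std::log(pl);
      ++nm;
    }
  }
  double val = (nm > 0) ? acc / nm : 0.0;
  return List::create(_["value"] = val, _["p"] = P, _["n_masked"] = nm);
}

// [[Rcpp::export]]
NumericVector cpp_masked_ce_bwd(double gscale, NumericVector P,
                                IntegerVector label, LogicalVector mask,
                                int nm, int C, int n) {
  NumericVector dx((size_t)C * n);
  if (nm == 0) return dx;
  const double* pp = P.begin();
  double* dp = dx.begin();
  double w = gscale / nm;
  for (int j = 0; j < n; ++j) {
    if (!mask[j]) continue;
    size_t o = (size_t)C * j;
    for (int c = 0; c < C; ++c) dp[o + c] = w * pp[o + c];
    dp[o + label[j]] -= w;
  }
  return dx;
}
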