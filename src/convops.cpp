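#include <Rcpp.h>
using namespace Rcpp;

// Activation layout used throughout the CNN engine:
//   a feature map batch is a (N * H * W) x C numeric matrix whose row index is
//   (n-1)*H*W + (w-1)*H + h   (column-major spatial order within each sample,
//   samples stacked sample-major).  All ops below assume this layout.

// im2col for stride-1 "same"-style integer padding.  Output is a
// (N * oH * oW) x (kh * kw * C) matrix; patch column index is
// (c-1)*kh*kw + (kj-1)*kh + ki, matching a (kh*kw*C) x F weight matrix.
// [[Rcpp::export]]
NumericMatrix nn_im2col(const NumericMatrix& act, int N, int H, int W, int C,
                        int kh, int kw, int pad) {
  const int oH = H + 2 * pad - kh + 1;
  const int oW = W + 2 * pad - kw + 1;
  const int K = kh * kw * C;
  NumericMatrix out((R_xlen_t)N * oH * oW, K);
  const double* a = act.begin();
  double* o = out.begin();
  const R_xlen_t arows = act.nrow();
  const R_xlen_t orows = out.nrow();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = c * kh * kw + kj * kh + ki;
        double* ocol = o + (R_xlen_t)col * orows;
        const double* acol = a + (R_xlen_t)c * arows;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t abase = (R_xlen_t)n * H * W;
          const R_xlen_t obase = (R_xlen_t)n * oH * oW;
          for (int ow = 0; ow < oW; ++ow) {
            const int iw = ow - pad + kj;
            double* op = ocol + obase + (R_xlen_t)ow * oH;
            if (iw < 0 || iw >= W) {
              for (int oh = 0; oh < oH; ++oh) op[oh] = 0.0;
              continue;
            }
            const double* ap = acol + abase + (R_xlen_t)iw * H;
            for (int oh = 0; oh < oH; ++oh) {
              const int ih = oh - pad + ki;
              op[oh] = (ih < 0 || ih >= H) ? 0.0 : ap[ih];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col: scatter patch-gradient columns back onto the input.
// [[Rcpp::export]]
NumericMatrix nn_col2im(const NumericMatrix& dcol, int N, int H, int W, int C,
                        int kh, int kw, int pad) {
  const int oH = H + 2 * pad - kh + 1;
  const int oW = W + 2 * pad - kw + 1;
  NumericMatrix dx((R_xlen_t)N * H * W, C);
  const double* d = dcol.begin();
  double* x = dx.begin();
  const R_xlen_t drows = dcol.nrow();
  const R_xlen_t xrows = dx.nrow();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = c * kh * kw + kj * kh + ki;
        const double* dc = d + (R_xlen_t)col * drows;
        double* xc = x + (R_xlen_t)c * xrows;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t dbase = (R_xlen_t)n * oH * oW;
          const R_xlen_t xbase = (R_xlen_t)n * H * W;
          for (int ow = 0; ow < oW; ++ow) {
            const int iw = ow - pad + kj;
            if (iw < 0 || iw >= W) continue;
            const double* dp = dc + dbase + (R_xlen_t)ow * oH;
            double* xp = xc + xbase + (R_xlen_t)iw * H;
            for (int oh = 0; oh < oH; ++oh) {
              const int ih = oh - pad + ki;
              if (ih >= 0 && ih < H) xp[ih] += dp[oh];
            }
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling with stride 2 (floor division on odd dims).  Returns the
// pooled map and the 1-based flat row index of each argmax for the backward
// pass.
// [[Rcpp::export]]
List nn_maxpool(const NumericMatrix& act, int N, int H, int W, int C) {
  const int oH = H / 2;
  const int oW = W / 2;
  NumericMatrix out((R_xlen_t)N * oH * oW, C);
  IntegerMatrix idx((R_xlen_t)N * oH * oW, C);
  const double* a = act.begin();
  const R_xlen_t arows = act.nrow();
  const R_xlen_t orows = out.nrow();
  for (int c = 0; c < C; ++c) {
    const double* ac = a + (R_xlen_t)c * arows;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t abase = (R_xlen_t)n * H * W;
      const R_xlen_t obase = (R_xlen_t)n * oH * oW;
      for (int ow = 0; ow < oW; ++ow) {
        for (int oh = 0; oh < oH; ++oh) {
          R_xlen_t best = abase + (R_xlen_t)(2 * ow) * H + 2 * oh;
          double bv = ac[best];
          const int dws = (2 * ow + 1 < W) ? 2 : 1;
          const int dhs = (2 * oh + 1 < H) ? 2 : 1;
          for (int dw = 0; dw < dws; ++dw) {
            for (int dh = 0; dh < dhs; ++dh) {
              const R_xlen_t p = abase + (R_xlen_t)(2 * ow + dw) * H + 2 * oh + dh;
              if (ac[p] > bv) { bv = ac[p]; best = p; }
            }
          }
          const R_xlen_t orow = obase + (R_xlen_t)ow * oH + oh;
          out[(R_xlen_t)c * orows + orow] = bv;
          idx[(R_xlen_t)c * orows + orow] = (int)(best + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix nn_maxpool_backward(const NumericMatrix& dout,
                                  const IntegerMatrix& idx,
                                  int N, int H, int W, int C) {
  NumericMatrix dx((R_xlen_t)N * H * W, C);
  const R_xlen_t orows = dout.nrow();
  const R_xlen_t xrows = dx.nrow();
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.begin() + (R_xlen_t)c * orows;
    const int* ic = idx.begin() + (R_xlen_t)c * orows;
    double* xc = dx.begin() + (R_xlen_t)c * xrows;
    for (R_xlen_t r = 0; r < orows; ++r) xc[ic[r] - 1] += dc[r];
  }
  return dx;
}

// In-place Adam update on one parameter tensor (par, m, v are modified).
// [[Rcpp::export]]
void nn_adam_leaf(NumericVector par, const NumericVector& grad,
                  NumericVector m, NumericVector v, double lr, double t,
                  double beta1, double beta2, double eps) {
  const R_xlen_t n = par.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * grad[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * grad[i] * grad[i];
    par[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// Batch-norm affine forward over columns: out = relu(gamma*zhat + beta),
// zhat = (z - mu) * inv_sd.  Returns the post-ReLU activations and zhat.
// [[Rcpp::export]]
List nn_bn_relu_forward(const NumericMatrix& z, const NumericVector& mu,
                        const NumericVector& inv_sd,
                        const NumericVector& gamma,
                        const NumericVector& beta) {
  const R_xlen_t nr = z.nrow();
  const int nc = z.ncol();
  NumericMatrix act(nr, nc), zhat(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double* zc = z.begin() + (R_xlen_t)c * nr;
    double* ac = act.begin() + (R_xlen_t)c * nr;
    double* hc = zhat.begin() + (R_xlen_t)c * nr;
    const double mm = mu[c], is = inv_sd[c], g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < nr; ++i) {
      const double h = (zc[i] - mm) * is;
      hc[i] = h;
      const double o = g * h + b;
      ac[i] = o > 0.0 ? o : 0.0;
    }
  }
  return List::create(_["act"] = act, _["zhat"] = zhat);
}

// Batch-norm backward.  dact is the gradient w.r.t. the post-ReLU
// activations; act are the cached post-ReLU activations (mask = act > 0).
// Returns dz plus the gamma/beta gradients.
// [[Rcpp::export]]
List nn_bn_relu_backward(const NumericMatrix& dact, const NumericMatrix& act,
                         const NumericMatrix& zhat,
                         const NumericVector& inv_sd,
                         const NumericVector& gamma) {
  const R_xlen_t nr = dact.nrow();
  const int nc = dact.ncol();
  NumericMatrix dz(nr, nc);
  NumericVector dgamma(nc), dbeta(nc);
  for (int c = 0; c < nc; ++c) {
    const double* dc = dact.begin() + (R_xlen_t)c * nr;
    const double* ac = act.begin() + (R_xlen_t)c * nr;
    const double* hc = zhat.begin() + (R_xlen_t)c * nr;
    double* oc = dz.begin() + (R_xlen_t)c * nr;
    double s1 = 0.0, s2 = 0.0, dg = 0.0, db = 0.0;
    for (R_xlen_t i = 0; i < nr; ++i) {
      const double d = ac[i] > 0.0 ? dc[i] : 0.0;
      dg += d * hc[i];
      db += d;
      const double dh = d * gamma[c];
      oc[i] = dh;              // stash dzhat; finished below
      s1 += dh;
      s2 += dh * hc[i];
    }
    dgamma[c] = dg; dbeta[c] = db;
    const double m1 = s1 / nr, m2 = s2 / nr, is = inv_sd[c];
    for (R_xlen_t i = 0; i < nr; ++i) {
      oc[i] = (oc[i] - m1 - hc[i] * m2) * is;
    }
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// column means and variances in one pass
// [[Rcpp::export]]
List nn_col_moments(const NumericMatrix& z) {
  const R_xlen_t nr = z.nrow();
  const int nc = z.ncol();
  NumericVector mu(nc), var(nc);
  for (int c = 0; c < nc; ++c) {
    const double* zc = z.begin() + (R_xlen_t)c * nr;
    double s = 0.0, ss = 0.0;
    for (R_xlen_t i = 0; i < nr; ++i) { s += zc[i]; ss += zc[i] * zc[i]; }
    const double m = s / nr;
    mu[c] = m;
    var[c] = ss / nr - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}
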