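// Compiled inner loops for the training path: valid-padding convolution,
// max pooling with winner tracking, and the Adam update. Array layout is
// R's column-major (batch, height, width, channel) flattening throughout.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_conv_forward(const NumericVector& x, const IntegerVector& xd,
                               const NumericVector& K, const IntegerVector& kd,
                               const NumericVector& bias) {
  const int B = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int kh = kd[0], kw = kd[1], Co = kd[3];
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericVector out(B * Ho * Wo * Co);
  for (int co = 0; co < Co; ++co) {
    const double bco = bias[co];
    double* op = out.begin() + (R_xlen_t)B * Ho * Wo * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)B * Ho * Wo; ++i) op[i] = bco;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xp = x.begin() + (R_xlen_t)B * H * W * ci;
      for (int kx = 0; kx < kw; ++kx) {
        for (int ky = 0; ky < kh; ++ky) {
          const double kv = K[ky + kh * (kx + kw * (ci + Ci * co))];
          if (kv == 0.0) continue;
          for (int xo = 0; xo < Wo; ++xo) {
            for (int yo = 0; yo < Ho; ++yo) {
              const double* xs = xp + (R_xlen_t)B * ((yo + ky) + H * (xo + kx));
              double* os = op + (R_xlen_t)B * (yo + Ho * xo);
              for (int b = 0; b < B; ++b) os[b] += kv * xs[b];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_backward(const NumericVector& x, const IntegerVector& xd,
                       const NumericVector& K, const IntegerVector& kd,
                       const NumericVector& dout) {
  const int B = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int kh = kd[0], kw = kd[1], Co = kd[3];
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericVector dx(x.size()), dK(K.size()), db(Co);
  for (int co = 0; co < Co; ++co) {
    const double* dp = dout.begin() + (R_xlen_t)B * Ho * Wo * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)B * Ho * Wo; ++i) acc += dp[i];
    db[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xp = x.begin() + (R_xlen_t)B * H * W * ci;
      double* dxp = dx.begin() + (R_xlen_t)B * H * W * ci;
      for (int kx = 0; kx < kw; ++kx) {
        for (int ky = 0; ky < kh; ++ky) {
          const double kv = K[ky + kh * (kx + kw * (ci + Ci * co))];
          double gk = 0.0;
          for (int xo = 0; xo < Wo; ++xo) {
            for (int yo = 0; yo < Ho; ++yo) {
              const double* xs = xp + (R_xlen_t)B * ((yo + ky) + H * (xo + kx));
              double* dxs = dxp + (R_xlen_t)B * ((yo + ky) + H * (xo + kx));
              const double* ds = dp + (R_xlen_t)B * (yo + Ho * xo);
              for (int b = 0; b < B; ++b) {
                gk += xs[b] * ds[b];
                dxs[b] += kv * ds[b];
              }
            }
          }
          dK[ky + kh * (kx + kw * (ci + Ci * co))] = gk;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dK"] = dK, _["db"] = db);
}

// Winners are recorded as 1-based linear indices into x, so the backward
// pass is a single scatter (windows never overlap).
// [[Rcpp::export]]
List cpp_pool_forward(const NumericVector& x, const IntegerVector& xd,
                      const int ph, const int pw) {
  const int B = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector out(B * Ho * Wo * C);
  NumericVector win(B * Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (R_xlen_t)B * H * W * c;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const R_xlen_t o0 = (R_xlen_t)B * (yo + Ho * (xo + Wo * c));
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          R_xlen_t bw = 0;
          for (int dx = 0; dx < pw; ++dx) {
            for (int dy = 0; dy < ph; ++dy) {
              const R_xlen_t ix =
                b + (R_xlen_t)B * ((yo * ph + dy) + H * (xo * pw + dx));
              const double v = xp[ix];
              if (v > best) {
                best = v;
                bw = ix + (R_xlen_t)B * H * W * c;
              }
            }
          }
          out[o0 + b] = best;
          win[o0 + b] = (double)(bw + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["win"] = win);
}

// One fused Adam step; returns fresh vectors (R objects are copy-on-write
// shared, so mutating the inputs in place would corrupt other references).
// [[Rcpp::export]]
List cpp_adam_update(const NumericVector& p, const NumericVector& m,
                     const NumericVector& v, const NumericVector& g,
                     const double lr, const double beta1, const double beta2,
                     const double bc1, const double bc2, const double eps) {
  const R_xlen_t n = p.size();
  NumericVector pn(n), mn(n), vn(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    mn[i] = beta1 * m[i] + (1 - beta1) * g[i];
    vn[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    pn[i] = p[i] - lr * (mn[i] / bc1) / (std::sqrt(vn[i] / bc2) + eps);
  }
  return List::create(_["p"] = pn, _["m"] = mn, _["v"] = vn);
}
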