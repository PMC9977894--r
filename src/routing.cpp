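#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Vote arrays are laid out (dim, types_in_group, positions, contributors),
// column-major as produced by R. Routing softmax-normalises agreement logits
// across the output types of the group, per contributor and position.

static inline double sq_scale(double r) { return r / (1.0 + r * r); }

static void apply_nonlin(const double* S, double* V, int d, int TP, int nonlin) {
  for (int j = 0; j < TP; ++j) {
    const double* s = S + (size_t)j * d;
    double* v = V + (size_t)j * d;
    double r2 = 0.0;
    for (int i = 0; i < d; ++i) r2 += s[i] * s[i];
    double r = std::sqrt(r2);
    double sc = (nonlin == 1) ? 1.0 / (1.0 + r) : sq_scale(r);
    for (int i = 0; i < d; ++i) v[i] = s[i] * sc;
  }
}

// [[Rcpp::export]]
List gcn_route_forward(NumericVector U, int d, int Tg, int P, int C,
                       int iters, int nonlin) {
  if (iters < 1) stop("routing requires at least one iteration");
  const double* u = U.begin();
  NumericVector Sv((size_t)d * Tg * P), Vv((size_t)d * Tg * P);
  NumericVector Bv((size_t)Tg * P * C);      // logits
  NumericVector Cw((size_t)Tg * P * C);      // couplings
  double* S = Sv.begin();
  double* V = Vv.begin();
  double* B = Bv.begin();
  double* Cc = Cw.begin();
  const size_t TP = (size_t)Tg * P;

  for (int it = 0; it < iters; ++it) {
    // couplings: softmax over the Tg axis for each (position, contributor)
    for (int c = 0; c < C; ++c) {
      for (int p = 0; p < P; ++p) {
        double* b = B + (size_t)c * TP + (size_t)p * Tg;
        double* cw = Cc + (size_t)c * TP + (size_t)p * Tg;
        double m = b[0];
        for (int t = 1; t < Tg; ++t) if (b[t] > m) m = b[t];
        double z = 0.0;
        for (int t = 0; t < Tg; ++t) { cw[t] = std::exp(b[t] - m); z += cw[t]; }
        for (int t = 0; t < Tg; ++t) cw[t] /= z;
      }
    }
    // dominant capsules: coupling-weighted vote sums
    std::fill(S, S + d * TP, 0.0);
    for (int c = 0; c < C; ++c) {
      const double* uc = u + (size_t)c * d * TP;
      const double* cw = Cc + (size_t)c * TP;
      for (size_t j = 0; j < TP; ++j) {
        double w = cw[j];
        const double* uj = uc + j * d;
        double* sj = S + j * d;
        for (int i = 0; i < d; ++i) sj[i] += w * uj[i];
      }
    }
    if (it < iters - 1) {
      // agreement update: logit += <vote, squashed dominant capsule>
      apply_nonlin(S, V, d, (int)TP, nonlin);
      for (int c = 0; c < C; ++c) {
        const double* uc = u + (size_t)c * d * TP;
        double* bc = B + (size_t)c * TP;
        for (size_t j = 0; j < TP; ++j) {
          const double* uj = uc + j * d;
          const double* vj = V + j * d;
          double a = 0.0;
          for (int i = 0; i < d; ++i) a += uj[i] * vj[i];
          bc[j] += a;
        }
      }
    }
  }
  apply_nonlin(S, V, d, (int)TP, nonlin);
  return List::create(_["S"] = Sv, _["V"] = Vv, _["Cw"] = Cw);
}

// Backward pass with couplings held fixed: gradients flow through the final
// weighted sum and the output nonlinearity only.
// [[Rcpp::export]]
NumericVector gcn_route_backward(NumericVector Cw, NumericVector S,
                                 NumericVector gV, int d, int Tg, int P, int C,
                                 int nonlin) {
  const size_t TP = (size_t)Tg * P;
  NumericVector gUv((size_t)d * TP * C);
  std::vector<double> gS(d * TP);
  const double* s = S.begin();
  const double* gv = gV.begin();
  const double eps = 1e-12;

  for (size_t j = 0; j < TP; ++j) {
    const double* sj = s + j * d;
    const double* gj = gv + j * d;
    double* out = gS.data() + j * d;
    double r2 = 0.0, dot = 0.0;
    for (int i = 0; i < d; ++i) { r2 += sj[i] * sj[i]; dot += sj[i] * gj[i]; }
    double r = std::sqrt(r2);
    if (nonlin == 1) {                      // f = s / (1 + r)
      double a = 1.0 / (1.0 + r);
      double b = (r > eps) ? dot / (r * (1.0 + r) * (1.0 + r)) : 0.0;
      for (int i = 0; i < d; ++i) out[i] = a * gj[i] - b * sj[i];
    } else {                                // f = s * r / (1 + r^2)
      double a = sq_scale(r);
      double sp = (1.0 - r2) / ((1.0 + r2) * (1.0 + r2));
      double b = (r > eps) ? sp * dot / r : 0.0;
      for (int i = 0; i < d; ++i) out[i] = a * gj[i] + b * sj[i];
    }
  }
  double* gU = gUv.begin();
  const double* cw = Cw.begin();
  for (int c = 0; c < C; ++c) {
    const double* cc = cw + (size_t)c * TP;
    double* guc = gU + (size_t)c * d * TP;
    for (size_t j = 0; j < TP; ++j) {
      double w = cc[j];
      const double* gsj = gS.data() + j * d;
      double* gu = guc + j * d;
      for (int i = 0; i < d; ++i) gu[i] = w * gsj[i];
    }
  }
  return gUv;
}
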