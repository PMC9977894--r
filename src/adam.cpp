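#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update on one weight tensor; m/v are the running moment
// estimates, c1/c2 the bias-correction factors for the current step.
// [[Rcpp::export]]
void gcn_adam_inplace(NumericVector p, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double b1, double b2,
                      double eps, double c1, double c2) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("parameter/gradient/state size mismatch");
  double* pp = p.begin(); const double* gg = g.begin();
  double* mm = m.begin(); double* vv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = gg[i];
    mm[i] = b1 * mm[i] + (1.0 - b1) * gi;
    vv[i] = b2 * vv[i] + (1.0 - b2) * gi * gi;
    pp[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
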