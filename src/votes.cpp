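#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Vote generation for one group of a capsule layer.
//
// X:    group slab (Dg, HW+1, B), column-major; the last spatial slot is a
//       zero pad column so out-of-image kernel taps gather zeros.
// doff: row offsets (length nt+1) of each in-group type inside the slab.
// idx:  (P0, K) 1-based map from output position to input slot.
// Wl:   contributor transformation matrices, c = (k-1)*nt + t, each
//       (m, d_t) with m = out_dim * out_types_per_group.
// Returns U (m, P0*B, C).

// [[Rcpp::export]]
NumericVector gcn_layer_votes(NumericVector X, IntegerVector doff,
                              IntegerMatrix idx, List Wl,
                              int m, int B, int HW, int P0) {
  const int K = idx.ncol();
  const int nt = doff.size() - 1;
  const int Dg = doff[nt];
  const int C = K * nt;
  const double one = 1.0, zero = 0.0;
  NumericVector Uv((size_t)m * P0 * B * C);
  std::vector<double> buf((size_t)Dg * P0 * B);
  const double* x = X.begin();
  double* U = Uv.begin();
  std::vector<const double*> wptr(C);
  std::vector<NumericMatrix> wm;
  wm.reserve(C);
  for (int c = 0; c < C; ++c) { wm.push_back(as<NumericMatrix>(Wl[c])); wptr[c] = wm[c].begin(); }
  const int PB = P0 * B;
  for (int k = 0; k < K; ++k) {
    const int* ik = &idx(0, k);
    for (int b = 0; b < B; ++b) {
      const double* xb = x + (size_t)b * Dg * (HW + 1);
      double* bb = buf.data() + (size_t)b * Dg * P0;
      for (int p = 0; p < P0; ++p)
        std::copy(xb + (size_t)(ik[p] - 1) * Dg, xb + (size_t)ik[p] * Dg,
                  bb + (size_t)p * Dg);
    }
    for (int t = 0; t < nt; ++t) {
      const int c = k * nt + t;
      const int dt = doff[t + 1] - doff[t];
      F77_CALL(dgemm)("N", "N", &m, &PB, &dt, &one, wptr[c], &m,
                      buf.data() + doff[t], &Dg, &zero,
                      U + (size_t)c * m * PB, &m FCONE FCONE);
    }
  }
  return Uv;
}

// Backward of the vote generation: weight gradients and input-slab gradient.
// gU: (m, P0*B, C). Returns list(gW = per-contributor matrices,
// gX = (Dg, HW+1, B) accumulated slab gradient; the pad column collects the
// out-of-image taps and is discarded by the caller).
// [[Rcpp::export]]
List gcn_layer_votes_backward(NumericVector gU, NumericVector X,
                              IntegerVector doff, IntegerMatrix idx, List Wl,
                              int m, int B, int HW, int P0) {
  const int K = idx.ncol();
  const int nt = doff.size() - 1;
  const int Dg = doff[nt];
  const double one = 1.0, zero = 0.0;
  const int PB = P0 * B;
  NumericVector gX((size_t)Dg * (HW + 1) * B);
  List gW(K * nt);
  std::vector<double> buf((size_t)Dg * P0 * B), gbuf((size_t)Dg * P0 * B);
  const double* x = X.begin();
  const double* gu = gU.begin();
  for (int k = 0; k < K; ++k) {
    const int* ik = &idx(0, k);
    for (int b = 0; b < B; ++b) {
      const double* xb = x + (size_t)b * Dg * (HW + 1);
      double* bb = buf.data() + (size_t)b * Dg * P0;
      for (int p = 0; p < P0; ++p)
        std::copy(xb + (size_t)(ik[p] - 1) * Dg, xb + (size_t)ik[p] * Dg,
                  bb + (size_t)p * Dg);
    }
    for (int t = 0; t < nt; ++t) {
      const int c = k * nt + t;
      const int dt = doff[t + 1] - doff[t];
      NumericMatrix w = as<NumericMatrix>(Wl[c]);
      NumericMatrix gw(m, dt);
      const double* guc = gu + (size_t)c * m * PB;
      // gW_c = gU_c * buf_t^T
      F77_CALL(dgemm)("N", "T", &m, &dt, &PB, &one, guc, &m,
                      buf.data() + doff[t], &Dg, &zero, gw.begin(),
                      &m FCONE FCONE);
      // gbuf_t = W_c^T * gU_c
      F77_CALL(dgemm)("T", "N", &dt, &PB, &m, &one, w.begin(), &m, guc, &m,
                      &zero, gbuf.data() + doff[t], &Dg FCONE FCONE);
      gW[c] = gw;
    }
    // scatter-add gathered-gradient columns back to input slots
    double* gx = gX.begin();
    for (int b = 0; b < B; ++b) {
      double* gxb = gx + (size_t)b * Dg * (HW + 1);
      const double* gb = gbuf.data() + (size_t)b * Dg * P0;
      for (int p = 0; p < P0; ++p) {
        double* dst = gxb + (size_t)(ik[p] - 1) * Dg;
        const double* src = gb + (size_t)p * Dg;
        for (int i = 0; i < Dg; ++i) dst[i] += src[i];
      }
    }
  }
  return List::create(_["gW"] = gW, _["gX"] = gX);
}
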