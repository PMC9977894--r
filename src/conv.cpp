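#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Plain 3x3 stride-1 convolution for the stem, on padded slabs
// A (ci, HW+1, B) with zero pad slot; W (co, ci, K); idx (P0, K).
// Z = sum_k W[,,k] %*% gather(A, idx[,k]) + b.

// [[Rcpp::export]]
NumericVector gcn_conv_forward(NumericVector A, IntegerMatrix idx,
                               NumericVector Wv, NumericVector bias,
                               int ci, int co, int B, int HW, int P0) {
  const int K = idx.ncol();
  const int PB = P0 * B;
  const double one = 1.0;
  NumericVector Z((size_t)co * PB);
  double* z = Z.begin();
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < P0; ++p) {
      double* zc = z + ((size_t)b * P0 + p) * co;
      for (int i = 0; i < co; ++i) zc[i] = bias[i];
    }
  std::vector<double> buf((size_t)ci * PB);
  const double* a = A.begin();
  for (int k = 0; k < K; ++k) {
    for (int b = 0; b < B; ++b) {
      const double* ab = a + (size_t)b * ci * (HW + 1);
      double* bb = buf.data() + (size_t)b * ci * P0;
      for (int p = 0; p < P0; ++p) {
        int slot = idx(p, k) - 1;
        std::copy(ab + (size_t)slot * ci, ab + (size_t)(slot + 1) * ci,
                  bb + (size_t)p * ci);
      }
    }
    F77_CALL(dgemm)("N", "N", &co, &PB, &ci, &one,
                    Wv.begin() + (size_t)k * co * ci, &co,
                    buf.data(), &ci, &one, z, &co FCONE FCONE);
  }
  return Z;
}

// [[Rcpp::export]]
List gcn_conv_backward(NumericVector A, IntegerMatrix idx, NumericVector Wv,
                       NumericVector gZ, int ci, int co, int B, int HW,
                       int P0) {
  const int K = idx.ncol();
  const int PB = P0 * B;
  const double one = 1.0, zero = 0.0;
  NumericVector gA((size_t)ci * (HW + 1) * B);
  NumericVector gW((size_t)co * ci * K);
  NumericVector gb(co);
  const double* gz = gZ.begin();
  for (int j = 0; j < PB; ++j)
    for (int i = 0; i < co; ++i) gb[i] += gz[(size_t)j * co + i];
  std::vector<double> buf((size_t)ci * PB), gbuf((size_t)ci * PB);
  const double* a = A.begin();
  for (int k = 0; k < K; ++k) {
    for (int b = 0; b < B; ++b) {
      const double* ab = a + (size_t)b * ci * (HW + 1);
      double* bb = buf.data() + (size_t)b * ci * P0;
      for (int p = 0; p < P0; ++p) {
        int slot = idx(p, k) - 1;
        std::copy(ab + (size_t)slot * ci, ab + (size_t)(slot + 1) * ci,
                  bb + (size_t)p * ci);
      }
    }
    F77_CALL(dgemm)("N", "T", &co, &ci, &PB, &one, gz, &co, buf.data(), &ci,
                    &zero, gW.begin() + (size_t)k * co * ci, &co FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &ci, &PB, &co, &one,
                    Wv.begin() + (size_t)k * co * ci, &co, gz, &co, &zero,
                    gbuf.data(), &ci FCONE FCONE);
    double* ga = gA.begin();
    for (int b = 0; b < B; ++b) {
      double* gab = ga + (size_t)b * ci * (HW + 1);
      const double* gb2 = gbuf.data() + (size_t)b * ci * P0;
      for (int p = 0; p < P0; ++p) {
        int slot = idx(p, k) - 1;
        double* dst = gab + (size_t)slot * ci;
        const double* src = gb2 + (size_t)p * ci;
        for (int i = 0; i < ci; ++i) dst[i] += src[i];
      }
    }
  }
  return List::create(_["gA"] = gA, _["gW"] = gW, _["gb"] = gb);
}
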