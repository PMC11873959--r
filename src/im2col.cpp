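#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Batched im2col gather with fused zero padding.
//
// X holds a batch of activations laid out as a (C, P, B) array (channels
// fastest). gidx has K * P entries, one per (kernel tap, output position),
// each either the 1-based linear index of the source position in the
// unpadded grid or 0 when the tap falls into the zero padding. The result
// is the (C*K, P*B) column matrix whose product with the (C_out, C*K)
// weight matrix realises a stride-1 same-padded convolution.
// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericVector X, IntegerVector gidx,
                           int C, int P, int B, int K) {
  NumericMatrix out(C * K, P * B);
  double *xo = REAL(out);
  const double *xi = REAL(X);
  const int *gi = INTEGER(gidx);
  const size_t CK = (size_t)C * K;
  for (int b = 0; b < B; ++b) {
    const double *xb = xi + (size_t)C * P * b;
    for (int p = 0; p < P; ++p) {
      double *col = xo + CK * ((size_t)P * b + p);
      const int *gp = gi + (size_t)K * p;
      if (C == 1) {
        for (int k = 0; k < K; ++k) {
          int s = gp[k];
          if (s > 0) col[k] = xb[s - 1];
        }
      } else {
        for (int k = 0; k < K; ++k) {
          int s = gp[k];
          if (s > 0)
            std::memcpy(col + (size_t)C * k, xb + (size_t)C * (s - 1),
                        sizeof(double) * C);
        }
      }
    }
  }
  return out;
}
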