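#include <Rcpp.h>
using namespace Rcpp;

// Unfold a (K x T x B) feature-map array into an im2col matrix of shape
// (K*klen) x (T*B) with zero padding of padl columns on the left of each
// trial, so a temporal convolution with same-length output becomes one GEMM.
// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericVector a, int K, int T, int B,
                           int klen, int padl) {
  NumericMatrix out(K * klen, T * B);
  const double *ap = a.begin();
  double *op = out.begin();
  for (int b = 0; b < B; ++b) {
    const double *trial = ap + (size_t)b * K * T;
    for (int t = 0; t < T; ++t) {
      double *col = op + ((size_t)b * T + t) * K * klen;
      for (int tau = 0; tau < klen; ++tau) {
        int src = t - padl + tau;
        double *dst = col + (size_t)tau * K;
        if (src >= 0 && src < T) {
          const double *s = trial + (size_t)src * K;
          for (int k = 0; k < K; ++k) dst[k] = s[k];
        } else {
          for (int k = 0; k < K; ++k) dst[k] = 0.0;
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_batch: scatter-add patch gradients back onto the
// (K x T x B) input array.
// [[Rcpp::export]]
NumericVector col2im_batch(NumericMatrix g, int K, int T, int B,
                           int klen, int padl) {
  NumericVector out((size_t)K * T * B);
  double *op = out.begin();
  const double *gp = g.begin();
  for (int b = 0; b < B; ++b) {
    double *trial = op + (size_t)b * K * T;
    for (int t = 0; t < T; ++t) {
      const double *col = gp + ((size_t)b * T + t) * K * klen;
      for (int tau = 0; tau < klen; ++tau) {
        int src = t - padl + tau;
        if (src < 0 || src >= T) continue;
        double *dst = trial + (size_t)src * K;
        const double *s = col + (size_t)tau * K;
        for (int k = 0; k < K; ++k) dst[k] += s[k];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(K, T, B);
  return out;
}

// Non-overlapping 1 x pool max pooling along the time axis of a
// (K x T x B) array (stored as K x (T*B) matrix). Returns the pooled values
// and the flat column index of each maximum for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd(NumericMatrix x, int K, int T, int B, int pool) {
  int To = T / pool;
  NumericMatrix out(K, To * B);
  IntegerMatrix idx(K, To * B);
  const double *xp = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int to = 0; to < To; ++to) {
      size_t ocol = (size_t)b * To + to;
      for (int k = 0; k < K; ++k) {
        double best = -1e300;
        int besti = -1;
        for (int p = 0; p < pool; ++p) {
          size_t icol = (size_t)b * T + to * pool + p;
          double v = xp[icol * K + k];
          if (v > best) { best = v; besti = (int)icol; }
        }
        out(k, ocol) = best;
        idx(k, ocol) = besti;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd(NumericMatrix dout, IntegerMatrix idx,
                          int K, int T, int B) {
  NumericMatrix dx(K, T * B);
  for (int j = 0; j < dout.ncol(); ++j) {
    for (int k = 0; k < dout.nrow(); ++k) {
      dx(k, idx(k, j)) += dout(k, j);
    }
  }
  return dx;
}
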