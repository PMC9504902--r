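// Single-precision cores for the sliding multitaper PSD and the
// trace-normalized class covariance; both are bandwidth-bound inner loops
// of the CSP-SVM pipeline.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// perm: samples x (comp*trial). Rcos/Rsin: (k*nf) x N taper-modulated DFT
// bases; binm: nbins x nf averaging matrix (already 1/count weighted).
// Returns (nbins*k-averaged) log band power, nbins x (comp*trial).
// [[Rcpp::export]]
arma::mat psd_core(const arma::mat &perm, int N, int stepn, int nwin,
                   const arma::mat &Rcos, const arma::mat &Rsin,
                   const arma::mat &binm, int ntaper) {
  fmat P = conv_to<fmat>::from(perm);
  fmat C = conv_to<fmat>::from(Rcos);
  fmat S = conv_to<fmat>::from(Rsin);
  fmat Bm = conv_to<fmat>::from(binm);
  const int nf = C.n_rows / ntaper;
  const size_t ncol = P.n_cols;
  mat out(Bm.n_rows * nwin, ncol);
  fmat A, B, pw(nf, ncol), pb;
  for (int w = 0; w < nwin; ++w) {
    size_t s0 = (size_t)w * stepn;
    A = C * P.rows(s0, s0 + N - 1);
    B = S * P.rows(s0, s0 + N - 1);
    A = square(A) + square(B);       // (ntaper*nf) x ncol
    pw.zeros();
    for (int j = 0; j < ntaper; ++j) {
      pw += A.rows((size_t)j * nf, (size_t)j * nf + nf - 1);
    }
    pw /= (float)ntaper;
    pb = log(Bm * pw);
    for (uword b = 0; b < pb.n_rows; ++b) {
      for (size_t c = 0; c < ncol; ++c) {
        out.at((size_t)w * pb.n_rows + b, c) = pb.at(b, c);
      }
    }
  }
  return out;
}

// data: trials x channels x samples array (R layout); idx: 1-based trial
// indices. Averages trace-normalized X X' over the selected trials.
// [[Rcpp::export]]
arma::mat class_cov_core(const Rcpp::NumericVector &data,
                         const Rcpp::IntegerVector &idx) {
  Rcpp::IntegerVector dims = data.attr("dim");
  const size_t ntr = dims[0], nch = dims[1], nsamp = dims[2];
  const double *dp = data.begin();
  fmat X(nch, nsamp);
  fmat S(nch, nch, fill::zeros);
  for (int t = 0; t < idx.size(); ++t) {
    size_t i = idx[t] - 1;
    for (size_t s = 0; s < nsamp; ++s) {
      const double *col = dp + i + s * ntr * nch;
      for (size_t c = 0; c < nch; ++c) X.at(c, s) = (float)col[c * ntr];
    }
    fmat C = X * X.t();
    S += C / trace(C);
  }
  return conv_to<mat>::from(S / (float)idx.size());
}
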