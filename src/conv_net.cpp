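// Fused forward/backward pass of the convolutional decoder.
//
// The temporal convolution is evaluated as klen shifted GEMMs on a
// zero-padded layout (each trial gets klen spare columns), avoiding an
// explicit im2col matrix. Two entry points share the templated core:
// cnn_pass (double precision, reference path used by the R-level forward
// and the gradient tests) and a single-precision training path
// (cnn_data_ptr + cnn_pass_train) whose epoch cost is bandwidth-bound, with
// the input held as a float matrix across a whole training run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

template <typename MT, typename VT, typename eT>
static Rcpp::List cnn_core(const MT &Xsel, const MT &W1, const VT &b1,
                           const MT &W2mat, const VT &b2, const MT &W3,
                           const VT &b3, const MT &W4, const VT &b4,
                           int T, int B, int pool, int klen, int padl,
                           const ivec &labels, bool backward) {
  const int K1 = W1.n_rows, K2 = W2mat.n_rows;
  const int To = T / pool;
  const int flat = K2 * To;
  const int Tp = T + klen;
  const size_t Np = (size_t)Tp * B;

  static thread_local MT A1p, A2p, P, H, dA2p, dA1p, dH;
  static thread_local umat idx;

  A1p.zeros(K1, Np);
  for (int b = 0; b < B; ++b) {
    A1p.cols((size_t)b * Tp, (size_t)b * Tp + T - 1) =
      W1 * Xsel.cols((size_t)b * T, (size_t)b * T + T - 1);
    A1p.cols((size_t)b * Tp, (size_t)b * Tp + T - 1).each_col() += b1;
  }
  A1p.transform([](eT v) { return v > 0 ? v : eT(0); });

  A2p.zeros(K2, Np);
  // column-blocked so the accumulator block stays cache-resident across taus
  const size_t blk = 4096;
  for (size_t c0 = 0; c0 < Np; c0 += blk) {
    size_t c1 = std::min(c0 + blk, Np) - 1;
    for (int tau = 0; tau < klen; ++tau) {
      long s = tau - padl;
      long lo = std::max<long>((long)c0, -s);
      long hi = std::min<long>((long)c1, (long)Np - 1 - s);
      if (lo > hi) continue;
      A2p.cols(lo, hi) +=
        W2mat.cols((size_t)tau * K1, (size_t)tau * K1 + K1 - 1) *
        A1p.cols(lo + s, hi + s);
    }
  }
  for (int b = 0; b < B; ++b) {
    A2p.cols((size_t)b * Tp, (size_t)b * Tp + T - 1).each_col() += b2;
  }
  // zero the (unused) pad columns so the ReLU mask silences them
  for (int b = 0; b < B; ++b) {
    A2p.cols((size_t)b * Tp + T, (size_t)(b + 1) * Tp - 1).zeros();
  }
  A2p.transform([](eT v) { return v > 0 ? v : eT(0); });

  P.set_size(K2, (size_t)To * B);
  idx.set_size(K2, (size_t)To * B);
  for (int b = 0; b < B; ++b) {
    for (int to = 0; to < To; ++to) {
      size_t oc = (size_t)b * To + to;
      for (int k = 0; k < K2; ++k) {
        eT best = -std::numeric_limits<eT>::infinity();
        size_t besti = 0;
        for (int p = 0; p < pool; ++p) {
          size_t ic = (size_t)b * Tp + (size_t)to * pool + p;
          eT v = A2p.at(k, ic);
          if (v > best) { best = v; besti = ic; }
        }
        P.at(k, oc) = best;
        idx.at(k, oc) = besti;
      }
    }
  }

  MT F(P.memptr(), flat, B, false, true);
  H = W3 * F;
  H.each_col() += b3;
  H.transform([](eT v) { return v > 0 ? v : eT(0); });
  MT logits = W4 * H;
  logits.each_col() += b4;

  Row<eT> mx = max(logits, 0);
  logits.each_row() -= mx;
  MT probs = exp(logits);
  Row<eT> Z = sum(probs, 0);
  probs.each_row() /= Z;

  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    double p = probs.at(labels[b], b);
    loss -= std::log(p > 1e-12 ? p : 1e-12);
  }
  loss /= B;

  if (!backward) {
    return Rcpp::List::create(
      Rcpp::_["loss"] = loss,
      Rcpp::_["probs"] = conv_to<mat>::from(probs.t()));
  }

  MT dlogits = probs;
  for (int b = 0; b < B; ++b) dlogits.at(labels[b], b) -= eT(1);
  dlogits /= eT(B);

  MT dW4 = dlogits * H.t();
  VT db4 = sum(dlogits, 1);
  dH = W4.t() * dlogits;
  dH.elem(find(H == eT(0))).zeros();
  MT dW3 = dH * F.t();
  VT db3 = sum(dH, 1);
  MT dF = W3.t() * dH;

  dA2p.zeros(K2, Np);
  {
    MT dP(dF.memptr(), K2, (size_t)To * B, false, true);
    for (size_t j = 0; j < dP.n_cols; ++j) {
      for (int k = 0; k < K2; ++k) {
        dA2p.at(k, idx.at(k, j)) += dP.at(k, j);
      }
    }
  }
  {
    eT *d = dA2p.memptr();
    const eT *a = A2p.memptr();
    for (size_t i = 0; i < dA2p.n_elem; ++i) if (a[i] == eT(0)) d[i] = eT(0);
  }

  MT dW2(K2, (size_t)K1 * klen, fill::zeros);
  dA1p.zeros(K1, Np);
  for (size_t c0b = 0; c0b < Np; c0b += blk) {
    size_t c1b = std::min(c0b + blk, Np) - 1;
    for (int tau = 0; tau < klen; ++tau) {
      long s = tau - padl;
      long lo = std::max<long>((long)c0b, -s);
      long hi = std::min<long>((long)c1b, (long)Np - 1 - s);
      if (lo > hi) continue;
      size_t w0 = (size_t)tau * K1, w1 = (size_t)tau * K1 + K1 - 1;
      dW2.cols(w0, w1) += dA2p.cols(lo, hi) * A1p.cols(lo + s, hi + s).t();
      dA1p.cols(lo + s, hi + s) += W2mat.cols(w0, w1).t() * dA2p.cols(lo, hi);
    }
  }
  VT db2(K2, fill::zeros);
  {
    eT *d = dA1p.memptr();
    const eT *a = A1p.memptr();
    for (size_t i = 0; i < dA1p.n_elem; ++i) if (a[i] == eT(0)) d[i] = eT(0);
  }
  MT dW1(K1, W1.n_cols, fill::zeros);
  VT db1(K1, fill::zeros);
  for (int b = 0; b < B; ++b) {
    size_t p0 = (size_t)b * Tp, p1 = (size_t)b * Tp + T - 1;
    size_t x0 = (size_t)b * T, x1 = (size_t)b * T + T - 1;
    dW1 += dA1p.cols(p0, p1) * Xsel.cols(x0, x1).t();
    db1 += sum(dA1p.cols(p0, p1), 1);
    db2 += sum(dA2p.cols(p0, p1), 1);
  }

  return Rcpp::List::create(
    Rcpp::_["loss"] = loss,
    Rcpp::_["probs"] = conv_to<mat>::from(probs.t()),
    Rcpp::_["dW1"] = conv_to<mat>::from(dW1),
    Rcpp::_["db1"] = conv_to<vec>::from(db1),
    Rcpp::_["dW2"] = conv_to<mat>::from(dW2),
    Rcpp::_["db2"] = conv_to<vec>::from(db2),
    Rcpp::_["dW3"] = conv_to<mat>::from(dW3),
    Rcpp::_["db3"] = conv_to<vec>::from(db3),
    Rcpp::_["dW4"] = conv_to<mat>::from(dW4),
    Rcpp::_["db4"] = conv_to<vec>::from(db4));
}

// Reference double-precision pass over an explicit channel x (time*trial)
// matrix.
// [[Rcpp::export]]
Rcpp::List cnn_pass(const arma::mat &Xmat, const arma::mat &W1,
                    const arma::vec &b1, const arma::mat &W2mat,
                    const arma::vec &b2, const arma::mat &W3,
                    const arma::vec &b3, const arma::mat &W4,
                    const arma::vec &b4, int T, int B, int pool,
                    int klen, int padl,
                    const arma::ivec &labels, bool backward) {
  return cnn_core<mat, vec, double>(Xmat, W1, b1, W2mat, b2, W3, b3, W4, b4,
                                    T, B, pool, klen, padl, labels, backward);
}

// Hold the training tensor as a single-precision matrix across batches.
// [[Rcpp::export]]
SEXP cnn_data_ptr(const arma::mat &Xmat) {
  fmat *p = new fmat(conv_to<fmat>::from(Xmat));
  Rcpp::XPtr<fmat> ptr(p, true);
  return ptr;
}

// Single-precision training pass on a batch of trials (1-based indices)
// gathered from a cnn_data_ptr handle.
// [[Rcpp::export]]
Rcpp::List cnn_pass_train(SEXP xptr, const arma::ivec &trial_idx,
                          const arma::mat &W1, const arma::vec &b1,
                          const arma::mat &W2mat, const arma::vec &b2,
                          const arma::mat &W3, const arma::vec &b3,
                          const arma::mat &W4, const arma::vec &b4,
                          int T, int pool, int klen, int padl,
                          const arma::ivec &labels, bool backward) {
  Rcpp::XPtr<fmat> X(xptr);
  const int B = trial_idx.n_elem;
  static thread_local fmat Xsel;
  Xsel.set_size(X->n_rows, (size_t)T * B);
  for (int b = 0; b < B; ++b) {
    size_t src = (size_t)(trial_idx[b] - 1) * T;
    Xsel.cols((size_t)b * T, (size_t)b * T + T - 1) =
      X->cols(src, src + T - 1);
  }
  fmat W1f = conv_to<fmat>::from(W1), W2f = conv_to<fmat>::from(W2mat),
       W3f = conv_to<fmat>::from(W3), W4f = conv_to<fmat>::from(W4);
  fvec b1f = conv_to<fvec>::from(b1), b2f = conv_to<fvec>::from(b2),
       b3f = conv_to<fvec>::from(b3), b4f = conv_to<fvec>::from(b4);
  return cnn_core<fmat, fvec, float>(Xsel, W1f, b1f, W2f, b2f, W3f, b3f,
                                     W4f, b4f, T, B, pool, klen, padl,
                                     labels, backward);
}
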