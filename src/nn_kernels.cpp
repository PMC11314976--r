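// Hot inner kernels of the CNN engine: im2col gather + affine + ReLU and the
// matching backward pass, plus max pooling. Index vectors are 1-based
// (precomputed in R at layer construction). Each convolution layer owns a
// C++-side cache (external pointer) holding the patch matrix and ReLU mask
// between the forward and backward pass, so no large intermediate crosses
// the R boundary.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvCache {
  arma::mat Xg;    // gathered patches, (C*k*Lout) x B
  arma::mat mask;  // ReLU mask, F x (Lout*B)
};

// [[Rcpp::export(name = ".conv_cache_new")]]
SEXP conv_cache_new() {
  XPtr<ConvCache> p(new ConvCache(), true);
  return p;
}

// [[Rcpp::export(name = ".conv_cache_ok")]]
bool conv_cache_ok(SEXP ptr) {
  return R_ExternalPtrAddr(ptr) != nullptr;
}

// forward: zero-pad, gather patch rows, multiply by the kernel matrix, add
// bias, rectify. Returns the activation (F x Lout*B).
// [[Rcpp::export(name = ".conv_fw_cpp")]]
arma::mat conv_fw_cpp(const arma::mat& X, const arma::uvec& pidx,
                      const arma::uvec& gidx, const arma::mat& W,
                      const arma::vec& b, int np, SEXP cache) {
  XPtr<ConvCache> cc(cache);
  const arma::uword B = X.n_cols, G = gidx.n_elem, n_in = pidx.n_elem;
  const arma::uword ck = W.n_cols;
  arma::mat Xp(np, B, arma::fill::zeros);
  for (arma::uword c = 0; c < B; ++c) {
    double* dst = Xp.colptr(c);
    const double* src = X.colptr(c);
    for (arma::uword i = 0; i < n_in; ++i) dst[pidx[i] - 1] = src[i];
  }
  cc->Xg.set_size(G, B);
  for (arma::uword c = 0; c < B; ++c) {
    const double* src = Xp.colptr(c);
    double* dst = cc->Xg.colptr(c);
    for (arma::uword i = 0; i < G; ++i) dst[i] = src[gidx[i] - 1];
  }
  arma::mat Xcol(cc->Xg.memptr(), ck, G / ck * B, false, true);
  arma::mat Y = W * Xcol;
  Y.each_col() += b;
  cc->mask.set_size(Y.n_rows, Y.n_cols);
  double* y = Y.memptr();
  double* m = cc->mask.memptr();
  for (arma::uword i = 0; i < Y.n_elem; ++i) {
    if (y[i] > 0) m[i] = 1.0; else { m[i] = 0.0; y[i] = 0.0; }
  }
  return Y;
}

// backward: mask the upstream gradient, accumulate kernel/bias gradients,
// back-project to the padded input and select the unpadded rows.
// [[Rcpp::export(name = ".conv_bw_cpp")]]
List conv_bw_cpp(const arma::mat& dOut, const arma::mat& W,
                 const arma::uvec& gidx, const arma::uvec& pidx, int np,
                 SEXP cache) {
  XPtr<ConvCache> cc(cache);
  const arma::uword Fl = W.n_rows, ck = W.n_cols, G = gidx.n_elem;
  const arma::uword B = cc->Xg.n_cols;
  arma::mat dY(const_cast<double*>(dOut.memptr()), Fl, dOut.n_elem / Fl,
               false, true);
  arma::mat dYm = dY % cc->mask;
  arma::mat Xcol(cc->Xg.memptr(), ck, G / ck * B, false, true);
  arma::mat dW = dYm * Xcol.t();
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dXcol = W.t() * dYm;
  arma::mat dXg(dXcol.memptr(), G, B, false, true);
  arma::mat dXp(np, B, arma::fill::zeros);
  for (arma::uword c = 0; c < B; ++c) {
    double* dst = dXp.colptr(c);
    const double* src = dXg.colptr(c);
    for (arma::uword i = 0; i < G; ++i) dst[gidx[i] - 1] += src[i];
  }
  const arma::uword n_in = pidx.n_elem;
  arma::mat dX(n_in, B);
  for (arma::uword c = 0; c < B; ++c) {
    const double* src = dXp.colptr(c);
    double* dst = dX.colptr(c);
    for (arma::uword i = 0; i < n_in; ++i) dst[i] = src[pidx[i] - 1];
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export(name = ".maxpool_fw_cpp")]]
List maxpool_fw_cpp(const arma::mat& X, const IntegerMatrix& cand) {
  const int M = cand.nrow(), Q = cand.ncol();
  const arma::uword B = X.n_cols;
  arma::mat A(M, B);
  IntegerMatrix win(M, B);
  for (arma::uword c = 0; c < B; ++c) {
    const double* src = X.colptr(c);
    for (int m = 0; m < M; ++m) {
      double best = src[cand(m, 0) - 1];
      int bq = 0;
      for (int q = 1; q < Q; ++q) {
        double v = src[cand(m, q) - 1];
        if (v > best) { best = v; bq = q; }
      }
      A(m, c) = best;
      win(m, c) = bq;
    }
  }
  return List::create(_["A"] = A, _["win"] = win);
}

// [[Rcpp::export(name = ".maxpool_bw_cpp")]]
arma::mat maxpool_bw_cpp(const arma::mat& dOut, const IntegerMatrix& win,
                         const IntegerMatrix& cand, int n_in) {
  const int M = cand.nrow();
  const arma::uword B = dOut.n_cols;
  arma::mat dX(n_in, B, arma::fill::zeros);
  for (arma::uword c = 0; c < B; ++c) {
    double* dst = dX.colptr(c);
    for (int m = 0; m < M; ++m)
      dst[cand(m, win(m, c)) - 1] += dOut(m, c);
  }
  return dX;
}

// Approximate entropy lives in entropy.cpp.
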