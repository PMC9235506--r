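// Hot numerical kernels: 1-D valid convolution as k shifted GEMMs,
// non-overlapping local max pooling, global max pooling, and an
// order-m Markov sequence sampler used by the synthetic-genome module.
// All random draws go through R's RNG so set.seed() governs them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X: L x Cin input; W: (k*Cin) x Cout with rows grouped by window offset
// (offset o occupies rows [o*Cin, (o+1)*Cin)); b: Cout.
// Returns Y: (L-k+1) x Cout.
// [[Rcpp::export]]
arma::mat nn_conv1d_fwd(const arma::mat& X, const arma::mat& W,
                        const arma::rowvec& b, const int k) {
  const int L = X.n_rows, Cin = X.n_cols;
  const int Lo = L - k + 1;
  if (Lo < 1) stop("input has %d rows but kernel size is %d", L, k);
  if ((int)W.n_rows != k * Cin)
    stop("weight rows (%d) != k*Cin (%d)", (int)W.n_rows, k * Cin);
  arma::mat Y(Lo, W.n_cols);
  Y.each_row() = b;
  for (int o = 0; o < k; ++o)
    Y += X.rows(o, o + Lo - 1) * W.rows(o * Cin, (o + 1) * Cin - 1);
  return Y;
}

// [[Rcpp::export]]
List nn_conv1d_bwd(const arma::mat& X, const arma::mat& W,
                   const arma::mat& dY, const int k) {
  const int Cin = X.n_cols;
  const int Lo = dY.n_rows;
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    dW.rows(o * Cin, (o + 1) * Cin - 1) = X.rows(o, o + Lo - 1).t() * dY;
    dX.rows(o, o + Lo - 1) += dY * W.rows(o * Cin, (o + 1) * Cin - 1).t();
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Non-overlapping max pooling along rows (stride = width); trailing
// rows that do not fill a block are dropped. idx holds 1-based row
// indices of the winners for the backward pass.
// [[Rcpp::export]]
List nn_maxpool_fwd(const arma::mat& X, const int width) {
  const int n = X.n_rows / width, C = X.n_cols;
  if (n < 1) stop("input has %d rows, pooling width %d", (int)X.n_rows, width);
  arma::mat Y(n, C);
  arma::imat idx(n, C);
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < n; ++i) {
      int best = i * width;
      double v = X(best, j);
      for (int o = 1; o < width; ++o) {
        const double w = X(i * width + o, j);
        if (w > v) { v = w; best = i * width + o; }
      }
      Y(i, j) = v;
      idx(i, j) = best + 1;
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat nn_maxpool_bwd(const arma::imat& idx, const arma::mat& dY,
                         const int L) {
  arma::mat dX(L, dY.n_cols, arma::fill::zeros);
  for (unsigned j = 0; j < dY.n_cols; ++j)
    for (unsigned i = 0; i < dY.n_rows; ++i)
      dX(idx(i, j) - 1, j) += dY(i, j);
  return dX;
}

// Global max over rows; ties resolved to the first (lowest) row index.
// [[Rcpp::export]]
List nn_gmax_fwd(const arma::mat& X) {
  const int C = X.n_cols;
  arma::rowvec y(C);
  arma::irowvec idx(C);
  for (int j = 0; j < C; ++j) {
    arma::uword w;
    y(j) = X.col(j).max(w);
    idx(j) = (int)w + 1;
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Order-m Markov chain over {1,2,3,4} with per-position mixture: with
// probability `signal` the next base follows `cum` (row = current
// context, columns = cumulative transition probabilities), otherwise
// the background distribution `bg_cum`. The initial m-base context is
// drawn from the background. Contexts index as base-4 numbers of the
// last m bases (most recent base is the least significant digit).
// [[Rcpp::export]]
IntegerVector markov_sequence(const int n, const arma::mat& cum,
                              const arma::rowvec& bg_cum, const int order,
                              const double signal) {
  IntegerVector out(n);
  const int S = cum.n_rows;
  int state = 0;
  int filled = 0;  // how many context positions are defined so far
  for (int i = 0; i < n; ++i) {
    int x;
    const bool use_model = filled >= order && (signal >= 1.0 ||
                           (signal > 0.0 && unif_rand() < signal));
    const double u = unif_rand();
    if (use_model) {
      x = 1 + (u > cum(state, 0)) + (u > cum(state, 1)) + (u > cum(state, 2));
    } else {
      x = 1 + (u > bg_cum(0)) + (u > bg_cum(1)) + (u > bg_cum(2));
    }
    out[i] = x;
    if (order > 0) {
      state = (state * 4 + (x - 1)) % S;
      if (filled < order) ++filled;
    }
  }
  return out;
}
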