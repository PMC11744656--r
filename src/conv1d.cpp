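// Causal dilated 1-D convolution kernels (forward and backward) used by the
// temporal blocks.  Layout: cubes are [channels, batch, length]; weights are
// [out_channels, in_channels, kernel_tap].  Left zero-padding is implicit:
// taps that would read before the first position are skipped, which equals
// padding by (k-1)*dilation and chomping the tail.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b, const int dilation) {
  const int B = X.n_cols, L = X.n_slices;
  const int Cout = W.n_rows, k = W.n_slices;
  arma::cube Y(Cout, B, L);
  arma::mat acc(Cout, B);
  for (int t = 0; t < L; ++t) {
    acc.each_col() = b;
    for (int j = 0; j < k; ++j) {
      const int s = t - (k - 1 - j) * dilation;
      if (s >= 0) acc += W.slice(j) * X.slice(s);
    }
    Y.slice(t) = acc;
  }
  return Y;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& dY, const arma::cube& X,
                    const arma::cube& W, const int dilation) {
  const int Cin = X.n_rows, B = X.n_cols, L = X.n_slices;
  const int Cout = W.n_rows, k = W.n_slices;
  arma::cube dX(Cin, B, L, arma::fill::zeros);
  arma::cube dW(Cout, Cin, k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int t = 0; t < L; ++t) {
    const arma::mat& dYt = dY.slice(t);
    db += arma::sum(dYt, 1);
    for (int j = 0; j < k; ++j) {
      const int s = t - (k - 1 - j) * dilation;
      if (s >= 0) {
        dW.slice(j) += dYt * X.slice(s).t();
        dX.slice(s) += W.slice(j).t() * dYt;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
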