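#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather-GEMM 2D convolution. Activations are stored as a C x P matrix
// where P = N*H*W with pixels flattened row-major per sample. IDX maps
// every output position to its input position for each of the K = k*k
// kernel offsets (1-based; 0 marks zero padding), so a convolution is a
// sum of K small GEMMs over gathered columns.

// [[Rcpp::export]]
arma::mat nn_conv_fw(const arma::mat& X, const arma::cube& W,
                     const arma::vec& b, const arma::imat& IDX) {
  const arma::uword K = W.n_slices;
  const arma::uword Cin = W.n_cols;
  const arma::uword Cout = W.n_rows;
  const arma::uword P = IDX.n_rows;
  arma::mat Y(Cout, P, arma::fill::zeros);
  arma::mat Xk(Cin, P);
  for (arma::uword k = 0; k < K; ++k) {
    Xk.zeros();
    for (arma::uword p = 0; p < P; ++p) {
      arma::sword j = IDX.at(p, k);
      if (j > 0) Xk.col(p) = X.col(j - 1);
    }
    Y += W.slice(k) * Xk;
  }
  Y.each_col() += b;
  return Y;
}

// Backward pass: returns gradients wrt input (dX), weights (dW) and bias
// (db). Within one kernel offset the output->input map is injective, so
// the scatter-add loop has no write conflicts.

// [[Rcpp::export]]
List nn_conv_bw(const arma::mat& X, const arma::cube& W,
                const arma::imat& IDX, const arma::mat& dY) {
  const arma::uword K = W.n_slices;
  const arma::uword Cin = W.n_cols;
  const arma::uword Cout = W.n_rows;
  const arma::uword P = IDX.n_rows;
  arma::mat dX(Cin, X.n_cols, arma::fill::zeros);
  arma::cube dW(Cout, Cin, K, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 1);
  arma::mat Xk(Cin, P);
  arma::mat T(Cin, P);
  for (arma::uword k = 0; k < K; ++k) {
    Xk.zeros();
    for (arma::uword p = 0; p < P; ++p) {
      arma::sword j = IDX.at(p, k);
      if (j > 0) Xk.col(p) = X.col(j - 1);
    }
    dW.slice(k) = dY * Xk.t();
    T = W.slice(k).t() * dY;
    for (arma::uword p = 0; p < P; ++p) {
      arma::sword j = IDX.at(p, k);
      if (j > 0) dX.col(j - 1) += T.col(p);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
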