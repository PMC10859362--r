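// BLAS-backed matrix products on flat tensors, avoiding the copies that
// matrix()/dim<- would make on large arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// y = x %*% w, with x a flat vector reinterpreted as (n, k) column-major.
// [[Rcpp::export]]
NumericMatrix cpp_matmul(NumericVector x, int n, NumericMatrix w) {
  const int k = w.nrow(), m = w.ncol();
  arma::mat X(x.begin(), n, k, false, true);
  arma::mat W(w.begin(), k, m, false, true);
  NumericMatrix out(n, m);
  arma::mat Y(out.begin(), n, m, false, true);
  Y = X * W;
  return out;
}

// crossprod(x, y) = t(x) %*% y with both flat, x (n, k), y (n, m).
// [[Rcpp::export]]
NumericMatrix cpp_crossprod(NumericVector x, int n, int k, NumericVector y,
                            int m) {
  arma::mat X(x.begin(), n, k, false, true);
  arma::mat Y(y.begin(), n, m, false, true);
  NumericMatrix out(k, m);
  arma::mat O(out.begin(), k, m, false, true);
  O = X.t() * Y;
  return out;
}

// y = x %*% t(w), x flat (n, m), w (k, m).
// [[Rcpp::export]]
NumericMatrix cpp_matmul_t(NumericVector x, int n, NumericMatrix w) {
  const int k = w.nrow(), m = w.ncol();
  arma::mat X(x.begin(), n, m, false, true);
  arma::mat W(w.begin(), k, m, false, true);
  NumericMatrix out(n, k);
  arma::mat Y(out.begin(), n, k, false, true);
  Y = X * W.t();
  return out;
}
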