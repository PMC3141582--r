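// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 2-D FFT backend (Armadillo); R's stockham fft is several times slower
// at 128^2 and the solver spends most of its time here

// [[Rcpp::export]]
arma::cx_mat fft2_cpp(const arma::cx_mat& x) {
  return arma::fft2(x);
}

// [[Rcpp::export]]
arma::cx_mat ifft2_cpp(const arma::cx_mat& x) {
  return arma::ifft2(x);
}
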