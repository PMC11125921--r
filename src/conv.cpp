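// 3x3x3 convolution via im2col + BLAS matrix multiply. The neighbour
// index matrix (n x 27, 0 = zero-padded out-of-bounds) is built and
// cached on the R side; columns of the im2col matrix are ordered with
// the tap index fastest within each input-channel block, matching the
// weight layout used by the R layers.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static void build_cols(const arma::mat &x, const IntegerMatrix &idx,
                       arma::mat &cols) {
  const int n = x.n_rows, cin = x.n_cols;
  for (int c = 0; c < cin; ++c) {
    const double *xc = x.colptr(c);
    for (int t = 0; t < 27; ++t) {
      double *dst = cols.colptr(t + 27 * c);
      const int *id = &idx(0, t);
      for (int i = 0; i < n; ++i)
        dst[i] = id[i] > 0 ? xc[id[i] - 1] : 0.0;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3_forward(const arma::mat &x, const IntegerMatrix &idx,
                            const arma::mat &W, const arma::vec &b) {
  arma::mat cols(x.n_rows, 27 * x.n_cols);
  build_cols(x, idx, cols);
  arma::mat y = cols * W;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_backward(const arma::mat &dy, const arma::mat &x,
                        const IntegerMatrix &idx, const arma::mat &W) {
  const int n = x.n_rows, cin = x.n_cols;
  arma::mat cols(n, 27 * cin);
  build_cols(x, idx, cols);
  arma::mat dW = cols.t() * dy;
  arma::rowvec db = arma::sum(dy, 0);
  arma::mat dcols = dy * W.t();
  arma::mat dx(n, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    double *dxc = dx.colptr(c);
    for (int t = 0; t < 27; ++t) {
      const double *s = dcols.colptr(t + 27 * c);
      const int *id = &idx(0, t);
      for (int i = 0; i < n; ++i)
        if (id[i] > 0) dxc[id[i] - 1] += s[i];
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW,
                      _["db"] = arma::vec(db.t()));
}
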