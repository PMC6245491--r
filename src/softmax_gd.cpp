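#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Full-batch gradient descent for softmax regression from zero
// initialisation. Case weights w collapse duplicated rows; the weighted
// gradient is mathematically identical to the expanded one. The row-wise
// max subtraction leaves the probabilities unchanged (shift invariance)
// and keeps exp() finite.
// [[Rcpp::export]]
Rcpp::List softmax_gd_cpp(const arma::mat& x, const arma::mat& yk,
                          const arma::vec& w, double lr, int epochs,
                          double l2) {
  const uword k = yk.n_cols;
  const uword f = x.n_cols;
  mat W(k, f, fill::zeros);
  vec b(k, fill::zeros);
  const double sw = accu(w);
  for (int it = 0; it < epochs; ++it) {
    mat z = x * W.t();
    z.each_row() += b.t();
    z.each_col() -= max(z, 1);
    mat p = exp(z);
    p.each_col() /= sum(p, 1);
    mat e = p - yk;
    e.each_col() %= w;
    W -= lr * (e.t() * x / sw + l2 * W);
    b -= lr * (sum(e, 0).t() / sw);
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("biases") = b);
}
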