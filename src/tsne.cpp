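// Inner loops of exact t-SNE. Quadratic in the number of points; kept in
// C++ so that corpora of a few thousand syllables embed in seconds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Conditional probabilities p_{j|i} whose row entropy matches
// log(perplexity), by binary search on the Gaussian precision per point.
// [[Rcpp::export]]
arma::mat tsne_cond_probs(const arma::mat& d2, double perplexity,
                          double tol = 1e-5, int max_iter = 50) {
  const uword n = d2.n_rows;
  const double target = std::log(perplexity);
  mat p(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, beta_lo = -datum::inf, beta_hi = datum::inf;
    rowvec di = d2.row(i);
    di(i) = 0.0;
    rowvec w(n, fill::zeros);
    for (int it = 0; it < max_iter; ++it) {
      w = exp(-di * beta);
      w(i) = 0.0; // exclude self
      double sw = accu(w);
      double h;
      if (sw <= 0) {
        h = 0.0;
      } else {
        double sdw = accu(di % w);
        h = std::log(sw) + beta * sdw / sw;
        w /= sw;
      }
      if (std::abs(h - target) < tol) break;
      if (h > target) {
        beta_lo = beta;
        beta = std::isfinite(beta_hi) ? (beta + beta_hi) / 2 : beta * 2;
      } else {
        beta_hi = beta;
        beta = std::isfinite(beta_lo) ? (beta + beta_lo) / 2 : beta / 2;
      }
    }
    p.row(i) = w;
    p(i, i) = 0.0;
  }
  return p;
}

// Gradient descent on the KL divergence with early exaggeration, momentum
// switch and adaptive gains; returns the final 2-D layout.
// [[Rcpp::export]]
arma::mat tsne_descent(const arma::mat& p_joint, const arma::mat& y0,
                       int n_iter, int exag_iters, double learning_rate,
                       double exaggeration) {
  const uword n = y0.n_rows;
  mat y = y0;
  mat inc(n, 2, fill::zeros);
  mat gains(n, 2, fill::ones);
  mat p = p_joint * exaggeration;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter == exag_iters + 1) p = p_joint;
    // Student-t similarities
    vec s = sum(square(y), 1);
    mat num = -2.0 * (y * y.t());
    num.each_col() += s;
    num.each_row() += s.t();
    num = 1.0 / (1.0 + num);
    num.diag().zeros();
    const double z = accu(num);
    mat pq = (p - num / z) % num;
    vec l = sum(pq, 1);
    mat grad = 4.0 * (y.each_col() % l - pq * y);

    const double momentum = (iter <= exag_iters) ? 0.5 : 0.8;
    for (uword k = 0; k < n * 2; ++k) {
      gains(k) = (std::signbit(grad(k)) != std::signbit(inc(k)))
                     ? gains(k) + 0.2
                     : gains(k) * 0.8;
      if (gains(k) < 0.01) gains(k) = 0.01;
    }
    inc = momentum * inc - learning_rate * (gains % grad);
    y += inc;
    y.each_row() -= mean(y, 0);
  }
  return y;
}
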