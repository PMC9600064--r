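// Diagonal neighborhood component analysis: objective and gradient.
//
// Feature weights w enter the metric as d_w(i, j) = sum_r w_r^2 |x_ir - x_jr|.
// Soft-neighbor probabilities p_ij = exp(-d_w(i, j)) / sum_{k != i} exp(-d_w(i, k))
// give the expected leave-one-out accuracy F(w) = (1/n) sum_i p_i - lambda sum_r w_r^2
// with p_i = sum_{j: y_j = y_i, j != i} p_ij. Returned for maximization;
// the R wrapper minimizes -F.
//
// Layout notes: the data are worked on transposed (features x observations)
// so absolute-difference columns are filled sequentially; the per-row
// softmax is shifted by the minimum distance for stability; softmax terms
// below 1e-12 of the row mass are skipped in the gradient accumulation
// (their contribution is below double rounding of the row sums).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List nca_objective(const arma::mat& X, const arma::ivec& y,
                         const arma::vec& w, const double lambda) {
  const arma::uword n = X.n_rows, k = X.n_cols;
  const arma::vec w2 = arma::square(w);
  const arma::mat Xt = X.t();          // k x n, columns are observations
  double f = 0.0;
  arma::vec grad(k, arma::fill::zeros);
  arma::mat A(k, n);                   // |x_j - x_i| columns, reused per i
  arma::vec d(n), p(n);

  for (arma::uword i = 0; i < n; ++i) {
    const double* xi = Xt.colptr(i);
    for (arma::uword j = 0; j < n; ++j) {
      const double* xj = Xt.colptr(j);
      double* aj = A.colptr(j);
      double acc = 0.0;
      for (arma::uword r = 0; r < k; ++r) {
        const double a = std::abs(xj[r] - xi[r]);
        aj[r] = a;
        acc += a * w2[r];
      }
      d(j) = acc;
    }
    d(i) = arma::datum::inf;
    const double dmin = d.min();
    p = arma::exp(-(d - dmin));
    p(i) = 0.0;
    const double z = arma::accu(p);
    if (z <= 0.0) continue;            // isolated point
    p /= z;

    double pi = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      if (j != i && y(j) == y(i)) pi += p(j);
    }
    f += pi;

    const double thresh = 1e-12;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i || p(j) < thresh) continue;
      const double coef = pi * p(j) - ((y(j) == y(i)) ? p(j) : 0.0);
      if (coef != 0.0) grad += coef * A.col(j);
    }
  }

  f = f / static_cast<double>(n) - lambda * arma::accu(w2);
  grad = 2.0 * (w % (grad / static_cast<double>(n))) - 2.0 * lambda * w;
  return Rcpp::List::create(Rcpp::Named("value") = f,
                            Rcpp::Named("gradient") = grad);
}
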