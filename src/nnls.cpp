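// Lawson-Hanson active-set nonnegative least squares.
// Solves min ||A x - b||_2 subject to x >= 0. The bootstrap attribution
// loop refits thousands of resampled spectra, hence the compiled solver
// and a multi-right-hand-side entry point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec nnls_one(const mat& A, const vec& b, double tol, int max_outer) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);

  int outer = 0;
  while (outer++ < max_outer) {
    // find most violated KKT multiplier among active (zero) coefficients
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
    if (t < 0 || wmax <= tol) break;
    passive[t] = true;

    for (;;) {
      uvec P;
      {
        std::vector<uword> idx;
        for (uword j = 0; j < n; ++j) if (passive[j]) idx.push_back(j);
        P = uvec(idx);
      }
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast);
      if (!ok) z = pinv(A.cols(P)) * b;

      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      // inner step: move toward z until a passive coefficient hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < P.n_elem; ++k)
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (uword k = 0; k < P.n_elem; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      for (uword k = 0; k < P.n_elem; ++k)
        if (x(P(k)) <= tol) { x(P(k)) = 0; passive[P(k)] = false; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export(name = ".nnls_solve")]]
arma::vec nnls_solve(const arma::mat& A, const arma::vec& b,
                     double tol = 1e-10, int max_outer = 0) {
  if (max_outer <= 0) max_outer = 3 * A.n_cols + 30;
  return nnls_one(A, b, tol, max_outer);
}

// [[Rcpp::export(name = ".nnls_solve_multi")]]
arma::mat nnls_solve_multi(const arma::mat& A, const arma::mat& B,
                           double tol = 1e-10, int max_outer = 0) {
  if (max_outer <= 0) max_outer = 3 * A.n_cols + 30;
  mat X(A.n_cols, B.n_cols);
  for (uword j = 0; j < B.n_cols; ++j)
    X.col(j) = nnls_one(A, B.col(j), tol, max_outer);
  return X;
}
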