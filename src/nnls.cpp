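// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Lawson-Hanson active-set non-negative least squares, solved independently
// for every column of Y against a shared sensing matrix A (channels x members).
// Returns the coefficient matrix X (members x n) and the per-column residual
// norm ||A x - y||_2. Tolerance is scaled by the magnitude of A'y so that the
// solver behaves identically across exposure scalings of the same problem.
// [[Rcpp::export(name = ".nnls_multi")]]
Rcpp::List nnls_multi(const arma::mat& A, const arma::mat& Y, int max_iter = 0) {
  const arma::uword m = A.n_rows, k = A.n_cols, n = Y.n_cols;
  if (Y.n_rows != m) Rcpp::stop("dimension mismatch between sensing matrix and data");
  if (max_iter <= 0) max_iter = 3 * (int)k + 10;

  arma::mat AtA = A.t() * A;
  arma::mat X(k, n, arma::fill::zeros);
  arma::vec resid(n);

  for (arma::uword j = 0; j < n; ++j) {
    arma::vec y = Y.col(j);
    arma::vec Aty = A.t() * y;
    double tol = 10.0 * arma::datum::eps * arma::norm(Aty, "inf") * (double)k;
    if (!arma::is_finite(tol)) tol = 0.0;

    arma::uvec passive(k, arma::fill::zeros);  // 1 = in passive (free) set
    arma::vec x(k, arma::fill::zeros);
    arma::vec w = Aty;                          // gradient of 1/2||Ax-y||^2 is -(Aty - AtA x)
    int iter = 0;
    while (true) {
      // find most violating zero-constrained variable
      double wmax = -arma::datum::inf;
      arma::sword t = -1;
      for (arma::uword i = 0; i < k; ++i)
        if (!passive(i) && w(i) > wmax) { wmax = w(i); t = (arma::sword)i; }
      if (t < 0 || wmax <= tol) break;
      passive((arma::uword)t) = 1;

      while (true) {
        arma::uvec P = arma::find(passive == 1);
        arma::vec z(k, arma::fill::zeros);
        arma::vec zp;
        bool ok = arma::solve(zp, AtA.submat(P, P), Aty.elem(P),
                              arma::solve_opts::likely_sympd);
        if (!ok) { // fall back to pseudoinverse on degenerate subproblem
          zp = arma::pinv(AtA.submat(P, P)) * Aty.elem(P);
        }
        z.elem(P) = zp;
        if (zp.min() > 0.0) { x = z; break; }
        // step toward z until a passive variable hits zero
        double alpha = arma::datum::inf;
        for (arma::uword idx = 0; idx < P.n_elem; ++idx) {
          arma::uword i = P(idx);
          if (z(i) <= 0.0) {
            double a = x(i) / (x(i) - z(i));
            if (a < alpha) alpha = a;
          }
        }
        if (!arma::is_finite(alpha)) alpha = 0.0;
        x += alpha * (z - x);
        for (arma::uword i = 0; i < k; ++i)
          if (passive(i) && x(i) <= tol) { passive(i) = 0; x(i) = 0.0; }
        if (++iter > max_iter) break;
      }
      w = Aty - AtA * x;
      if (++iter > max_iter) break;
    }
    X.col(j) = x;
    resid(j) = arma::norm(A * x - y, 2);
  }
  return Rcpp::List::create(Rcpp::Named("x") = X, Rcpp::Named("residual") = resid);
}
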