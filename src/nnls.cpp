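// Row-wise non-negative least squares by the Lawson-Hanson active-set method.
// Solves, for every row x of X (a voxel's attenuation across energies),
//   min_{c >= 0} || c * M - x ||_2
// where M is the materials-by-energies sensitivity matrix. Intended for small
// material counts (<= number of energies); each voxel's problem is tiny.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat nnls_rows_cpp(const arma::mat& X, const arma::mat& M, double tol) {
  const arma::uword n = X.n_rows, m = M.n_rows;
  const arma::mat A = M.t();  // energies x materials
  arma::mat C(n, m, arma::fill::zeros);

  for (arma::uword i = 0; i < n; ++i) {
    arma::vec b = X.row(i).t();
    arma::vec c(m, arma::fill::zeros);
    std::vector<bool> passive(m, false);
    arma::uword np = 0;
    arma::vec wgrad = A.t() * b;  // gradient of -0.5*residual^2 at c = 0
    int outer = 0;
    while (np < m && ++outer <= 3 * (int)m + 10) {
      // most positive gradient among active (zero) coefficients
      double wmax = tol;
      int t = -1;
      for (arma::uword j = 0; j < m; ++j)
        if (!passive[j] && wgrad(j) > wmax) { wmax = wgrad(j); t = (int)j; }
      if (t < 0) break;
      passive[t] = true;
      ++np;
      // inner loop: restore feasibility on the passive set
      for (;;) {
        arma::uvec pidx(np);
        arma::uword q = 0;
        for (arma::uword j = 0; j < m; ++j)
          if (passive[j]) pidx(q++) = j;
        arma::vec z = arma::solve(A.cols(pidx), b);
        if (z.min() > 0) {
          c.zeros();
          c.elem(pidx) = z;
          break;
        }
        double alpha = 1.0;
        for (arma::uword k = 0; k < np; ++k)
          if (z(k) <= 0) {
            const double cj = c(pidx(k));
            const double a = cj / (cj - z(k));
            if (a < alpha) alpha = a;
          }
        for (arma::uword k = 0; k < np; ++k)
          c(pidx(k)) += alpha * (z(k) - c(pidx(k)));
        arma::uword np2 = 0;
        for (arma::uword j = 0; j < m; ++j) {
          if (passive[j] && c(j) <= tol) { passive[j] = false; c(j) = 0.0; }
          if (passive[j]) ++np2;
        }
        np = np2;
        if (np == 0) break;
      }
      if (np == 0) break;
      wgrad = A.t() * (b - A * c);
    }
    C.row(i) = c.t();
  }
  return C;
}
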