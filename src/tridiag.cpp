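#include <Rcpp.h>
using namespace Rcpp;

// Per-track Gaussian log-densities under one diffusive state, one dimension.
//
// X: Nmax x M matrix of zero-padded displacement vectors (column = track).
// N: number of displacements of each track (quad form and log-determinant
//    use only the leading N[m] rows of column m).
// a, b: diagonal and off-diagonal of the tridiagonal Toeplitz covariance.
//
// The LDL^T pivots of the length-Nmax matrix factorize every leading
// principal submatrix, so one pivot recursion serves all track lengths;
// the quadratic form comes from forward substitution against the unit
// bidiagonal factor.
// [[Rcpp::export(name = ".tridiag_loglik")]]
NumericVector tridiag_loglik(NumericMatrix X, IntegerVector N,
                             double a, double b) {
  const int Nmax = X.nrow(), M = X.ncol();
  std::vector<double> d(Nmax), cld(Nmax), l(Nmax);
  d[0] = a;
  if (a <= 0.0) stop("tridiagonal factorization breakdown (diag %g, off %g)",
                     a, b);
  cld[0] = std::log(a);
  for (int i = 1; i < Nmax; ++i) {
    l[i] = b / d[i - 1];
    d[i] = a - b * l[i];
    if (d[i] <= 0.0)
      stop("tridiagonal factorization breakdown (diag %g, off %g)", a, b);
    cld[i] = cld[i - 1] + std::log(d[i]);
  }
  const double LOG2PI = std::log(2.0 * M_PI);
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    const int n = N[m];
    double quad = 0.0, yprev = 0.0;
    for (int i = 0; i < n; ++i) {
      double y = X(i, m) - (i > 0 ? l[i] * yprev : 0.0);
      quad += y * y / d[i];
      yprev = y;
    }
    out[m] = -0.5 * (n * LOG2PI + cld[n - 1] + quad);
  }
  return out;
}
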