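#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for L1-penalized least squares on precomputed
// moments (covariance updates): C = X'X/n, b = X'y/n for the centered
// design.  Warm starts along a decreasing lambda path; convergence on the
// maximum coefficient change per sweep.

// [[Rcpp::export]]
NumericMatrix cd_path_cpp(NumericMatrix C, NumericVector b,
                          NumericVector lambda, double tol,
                          int max_sweeps) {
  const int p = b.size();
  const int L = lambda.size();
  NumericMatrix out(p, L);
  std::vector<double> beta(p, 0.0);
  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double rho = b[j];
        for (int k = 0; k < p; ++k)
          if (k != j) rho -= C(j, k) * beta[k];
        double bj = 0.0;
        if (rho > lam) bj = (rho - lam) / C(j, j);
        else if (rho < -lam) bj = (rho + lam) / C(j, j);
        const double d = std::fabs(bj - beta[j]);
        if (d > delta) delta = d;
        beta[j] = bj;
      }
      if (delta < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
  }
  return out;
}
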