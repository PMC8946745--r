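#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

//' Weighted lasso coordinate descent (internal)
//'
//' Minimizes (1/2n) * sum_i v_i (z_i - x_i' beta)^2 + lambda * sum_j pf_j |beta_j|.
//' Columns with pf_j = 0 (intercept, covariates) are unpenalized. The caller is
//' responsible for any standardization; no intercept is added implicitly.
//'
//' Sweep strategy: one full cycle over all columns, then repeated cycles over
//' the current nonzero set until the max absolute coefficient change falls
//' below tol, then a final full cycle to confirm; repeats until the full cycle
//' itself is quiet. This is the classic covariance-free active-set scheme.
//'
//' @noRd
// [[Rcpp::export(name = ".cd_wls")]]
Rcpp::List cd_wls(const arma::mat& X, const arma::vec& z, const arma::vec& v,
                  double lambda, const arma::vec& pf, arma::vec beta,
                  double tol, int max_iter) {
  const uword n = X.n_rows, p = X.n_cols;
  // column curvature d_j = x_j' V x_j / n
  vec d(p);
  for (uword j = 0; j < p; ++j) d(j) = dot(square(X.col(j)), v) / double(n);
  vec r = z - X * beta;  // residual
  int iter = 0;
  bool converged = false;
  std::vector<uword> ever;  // columns touched with nonzero beta (plus unpenalized)
  auto sweep = [&](const std::vector<uword>& idx) -> double {
    double delta = 0.0;
    for (uword k = 0; k < idx.size(); ++k) {
      uword j = idx[k];
      if (d(j) <= 0) continue;
      double num = dot(X.col(j) % v, r) / double(n) + beta(j) * d(j);
      double bn = soft_threshold(num, lambda * pf(j)) / d(j);
      double diff = bn - beta(j);
      if (diff != 0.0) {
        r -= X.col(j) * diff;
        beta(j) = bn;
        double a = std::abs(diff);
        if (a > delta) delta = a;
      }
    }
    return delta;
  };
  std::vector<uword> all(p);
  for (uword j = 0; j < p; ++j) all[j] = j;
  while (iter < max_iter) {
    double dfull = sweep(all);
    ++iter;
    if (dfull < tol) { converged = true; break; }
    // iterate on active (nonzero or unpenalized) set
    while (iter < max_iter) {
      std::vector<uword> act;
      for (uword j = 0; j < p; ++j)
        if (beta(j) != 0.0 || pf(j) == 0.0) act.push_back(j);
      double da = sweep(act);
      ++iter;
      if (da < tol) break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
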