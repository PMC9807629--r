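// Pairwise-update (SMO-style) solver for the SVDD dual:
//   maximize  sum_i a_i K_ii - sum_ij a_i a_j K_ij
//   s.t.      sum_i a_i = 1,  0 <= a_i <= C
// At the optimum the gradient g_i = K_ii - 2 (K a)_i satisfies
//   g_i = lambda on 0 < a_i < C, g_i <= lambda at a_i = 0,
//   g_i >= lambda at a_i = C,
// so the maximal KKT violation max_{a<C} g - min_{a>0} g drives both the
// working-set choice and the stopping rule.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".svdd_solve_dual_cpp")]]
Rcpp::List svdd_solve_dual_cpp(const arma::mat& K, double C,
                               double tol = 1e-8, int max_iter = 0) {
  const int n = K.n_rows;
  if (max_iter <= 0) max_iter = std::max(200 * n, 2000);
  vec alpha(n, fill::value(1.0 / n));
  vec diagK = K.diag();
  vec g = diagK - 2.0 * (K * alpha);

  bool converged = false;
  int it = 0;
  const double eps = 1e-12;
  for (it = 0; it < max_iter; ++it) {
    // working set: largest gradient among up-movable, smallest among
    // down-movable coordinates
    int i = -1, j = -1;
    double gmax = -datum::inf, gmin = datum::inf;
    for (int t = 0; t < n; ++t) {
      if (alpha[t] < C - eps && g[t] > gmax) { gmax = g[t]; i = t; }
      if (alpha[t] > eps && g[t] < gmin) { gmin = g[t]; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { converged = true; break; }

    double eta = 2.0 * (K(i, i) - 2.0 * K(i, j) + K(j, j));
    double step_max = std::min(C - alpha[i], alpha[j]);
    double delta;
    if (eta > eps) {
      delta = std::min((gmax - gmin) / eta, step_max);
    } else {
      delta = step_max; // flat or concave-degenerate direction: full step
    }
    if (delta <= 0) { converged = true; break; }
    alpha[i] += delta;
    alpha[j] -= delta;
    g -= 2.0 * delta * (K.col(i) - K.col(j));
  }
  double obj = dot(alpha, diagK) - as_scalar(alpha.t() * K * alpha);
  return Rcpp::List::create(
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export(name = ".rbf_kernel_cpp")]]
arma::mat rbf_kernel_cpp(const arma::mat& X, const arma::mat& Y,
                         double sigma) {
  vec xn = sum(square(X), 1);
  vec yn = sum(square(Y), 1);
  mat D = repmat(xn, 1, Y.n_rows) + repmat(yn.t(), X.n_rows, 1)
          - 2.0 * X * Y.t();
  D.clamp(0.0, datum::inf);
  return exp(-D / (sigma * sigma));
}

// [[Rcpp::export(name = ".sqdist_cpp")]]
arma::mat sqdist_cpp(const arma::mat& X, const arma::mat& Y) {
  vec xn = sum(square(X), 1);
  vec yn = sum(square(Y), 1);
  mat D = repmat(xn, 1, Y.n_rows) + repmat(yn.t(), X.n_rows, 1)
          - 2.0 * X * Y.t();
  D.clamp(0.0, datum::inf);
  return D;
}
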