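// Affinity propagation by responsibility/availability message passing.
// S is the n x n similarity matrix with the preference on the diagonal.
// Messages are damped by `damping`; the run stops when the exemplar set is
// unchanged for `conv_iter` consecutive iterations or `max_iter` is hit.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".ap_cluster_cpp")]]
Rcpp::List ap_cluster_cpp(const arma::mat& S, double damping,
                          int max_iter, int conv_iter) {
  const int n = S.n_rows;
  mat R(n, n, fill::zeros), A(n, n, fill::zeros);
  uvec exemplars_prev;
  int stable = 0, it = 0;
  bool converged = false;

  for (it = 0; it < max_iter; ++it) {
    // responsibilities: R(i,k) = S(i,k) - max_{k' != k} (A + S)(i,k')
    mat AS = A + S;
    vec m1(n), m2(n);
    uvec i1(n);
    for (int i = 0; i < n; ++i) {
      double best = -datum::inf, second = -datum::inf; int bi = 0;
      for (int k = 0; k < n; ++k) {
        double v = AS(i, k);
        if (v > best) { second = best; best = v; bi = k; }
        else if (v > second) { second = v; }
      }
      m1[i] = best; m2[i] = second; i1[i] = bi;
    }
    mat Rnew = S;
    Rnew.each_col() -= m1;
    for (int i = 0; i < n; ++i) Rnew(i, i1[i]) = S(i, i1[i]) - m2[i];
    R = damping * R + (1.0 - damping) * Rnew;

    // availabilities: A(i,k) = min(0, R(k,k) + sum_{i' not in {i,k}} max(0,R(i',k)))
    //                 A(k,k) = sum_{i' != k} max(0, R(i',k))
    mat Rp = clamp(R, 0.0, datum::inf);
    Rp.diag() = R.diag(); // keep self-responsibility as-is in the column sum
    rowvec csum = sum(Rp, 0);
    mat Anew = repmat(csum, n, 1) - Rp;
    vec dA = Anew.diag(); // = sum_{i' != k} max(0, R(i',k))
    Anew.clamp(-datum::inf, 0.0);
    Anew.diag() = dA;
    A = damping * A + (1.0 - damping) * Anew;

    uvec ex = find(A.diag() + R.diag() > 0);
    if (ex.n_elem == exemplars_prev.n_elem &&
        (ex.n_elem == 0 || all(ex == exemplars_prev))) {
      if (++stable >= conv_iter && ex.n_elem > 0) {
        converged = true;
        ++it;
        break;
      }
    } else {
      stable = 0;
    }
    exemplars_prev = ex;
  }

  uvec ex = find(A.diag() + R.diag() > 0);
  if (ex.n_elem == 0) {
    // degenerate run: fall back to the single best criterion point
    ex = uvec{ (A.diag() + R.diag()).index_max() };
    converged = false;
  }
  // assignment: each point joins the exemplar with maximal similarity;
  // exemplars label themselves
  uvec labels(n);
  for (int i = 0; i < n; ++i) {
    double best = -datum::inf; int bk = 0;
    for (unsigned int e = 0; e < ex.n_elem; ++e) {
      if (S(i, ex[e]) > best) { best = S(i, ex[e]); bk = e; }
    }
    labels[i] = bk;
  }
  for (unsigned int e = 0; e < ex.n_elem; ++e) labels[ex[e]] = e;

  return Rcpp::List::create(
    Rcpp::Named("labels") = Rcpp::IntegerVector(labels.begin(), labels.end()),
    Rcpp::Named("exemplars") = Rcpp::IntegerVector(ex.begin(), ex.end()),
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
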