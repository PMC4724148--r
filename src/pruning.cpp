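// Felsenstein pruning over a codon alignment with per-branch transition
// matrices built from symmetric eigendecompositions of the reversible
// generator.  One decomposition is shared by every branch with the same
// (kappa, omega, pi); branches select theirs through dec_idx.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// edge: postorder edge matrix (1-based ape node ids, parent/child columns);
// tip_states: n_tip x n_pat, 1-based sense-codon index, 0 = missing;
// V, lambda, sqp: eigendecomposition pieces, one slice/column per distinct
// parameter set; pi: root frequencies; weights: pattern multiplicities.
// [[Rcpp::export]]
Rcpp::List prune_loglik_cpp(const arma::imat& edge,
                            const int n_tip,
                            const arma::vec& tlen,
                            const arma::ivec& dec_idx,
                            const arma::cube& V,
                            const arma::mat& lambda,
                            const arma::vec& sqp,
                            const arma::vec& pi,
                            const arma::imat& tip_states,
                            const arma::vec& weights) {
  const uword nc = pi.n_elem;
  const uword n_pat = tip_states.n_cols;
  const uword n_edge = edge.n_rows;
  uword n_node = 0;
  for (uword e = 0; e < n_edge; ++e) {
    n_node = std::max(n_node, (uword) edge(e, 0));
    n_node = std::max(n_node, (uword) edge(e, 1));
  }

  cube part(nc, n_pat, n_node, fill::ones);
  mat logscale(n_pat, n_node, fill::zeros);

  mat P(nc, nc), contrib(nc, n_pat);
  for (uword e = 0; e < n_edge; ++e) {
    const uword p = edge(e, 0) - 1;
    const uword c = edge(e, 1) - 1;
    const uword k = dec_idx(e) - 1;
    // P(t) = D^{-1/2} V exp(Lambda t) V' D^{1/2}
    const mat Vk = V.slice(k);
    const vec ex = exp(lambda.col(k) * tlen(e));
    P = Vk * diagmat(ex) * Vk.t();
    P.each_row() %= sqp.t();
    P.each_col() /= sqp;
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });

    if (c < (uword) n_tip) {
      for (uword s = 0; s < n_pat; ++s) {
        const int st = tip_states(c, s);
        if (st > 0)
          contrib.col(s) = P.col(st - 1);
        else
          contrib.col(s).ones();
      }
    } else {
      contrib = P * part.slice(c);
      logscale.col(p) += logscale.col(c);
    }
    part.slice(p) %= contrib;
    // per-pattern rescale to dodge underflow on deep trees
    for (uword s = 0; s < n_pat; ++s) {
      const double m = part.slice(p).col(s).max();
      if (m > 0.0 && m != 1.0) {
        part.slice(p).col(s) /= m;
        logscale(s, p) += std::log(m);
      }
    }
  }

  const uword root = edge(n_edge - 1, 0) - 1;
  vec sitell(n_pat);
  for (uword s = 0; s < n_pat; ++s)
    sitell(s) = std::log(dot(pi, part.slice(root).col(s))) + logscale(s, root);

  return Rcpp::List::create(
      Rcpp::Named("total") = dot(weights, sitell),
      Rcpp::Named("site_loglik") = sitell);
}
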