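#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

// Transition probability matrix P(t) = exp(Q t), scaling-and-squaring.
// Tiny negative entries from roundoff are clamped and rows renormalized.
static arma::mat pmat(const arma::mat& Q, const double t) {
  arma::mat P = arma::expmat(Q * t);
  P.clamp(0.0, arma::datum::inf);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    double s = arma::accu(P.row(i));
    if (s > 0) P.row(i) /= s;
  }
  return P;
}

// P(t) per edge, cached by unique branch length (equal-branch trees hit the
// cache once; ultrametric trees fall back to one expm per distinct length).
static std::vector<arma::mat> edge_pmats(const arma::mat& Q, const arma::vec& len) {
  std::map<double, arma::mat> cache;
  std::vector<arma::mat> out(len.n_elem);
  for (arma::uword e = 0; e < len.n_elem; ++e) {
    auto it = cache.find(len[e]);
    if (it == cache.end())
      it = cache.emplace(len[e], pmat(Q, len[e])).first;
    out[e] = it->second;
  }
  return out;
}

// [[Rcpp::export(name = ".pmat_cpp")]]
arma::mat pmat_cpp(const arma::mat& Q, const double t) { return pmat(Q, t); }

// Felsenstein pruning over a postorder edge list (ape 1-based node ids:
// tips 1..n, root n+1). tipL: n_tip x k partial-likelihood rows for tips.
// Returns rescaled root partials and the accumulated log scaler, so the
// caller can apply any root treatment.
// [[Rcpp::export(name = ".pruning_partials_cpp")]]
Rcpp::List pruning_partials_cpp(const arma::imat& edge, const arma::vec& len,
                                const int n_tip, const arma::mat& tipL,
                                const arma::mat& Q) {
  const int k = Q.n_rows;
  const int n_node = n_tip + edge.n_rows / 2 + 1;  // binary rooted tree
  arma::mat part(n_node, k, arma::fill::ones);
  part.rows(0, n_tip - 1) = tipL;
  double logscale = 0.0;
  const std::vector<arma::mat> P = edge_pmats(Q, len);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int par = edge(e, 0) - 1, chi = edge(e, 1) - 1;
    arma::rowvec d = part.row(chi);
    const double m = d.max();
    if (m <= 0.0)
      return Rcpp::List::create(Rcpp::Named("loglik_impossible") = true);
    d /= m;
    logscale += std::log(m);
    part.row(par) %= (P[e] * d.t()).t();
  }
  const int root = n_tip;  // ape root id n_tip + 1
  return Rcpp::List::create(
      Rcpp::Named("root_partial") = part.row(root).t(),
      Rcpp::Named("log_scaler") = logscale,
      Rcpp::Named("loglik_impossible") = false);
}
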