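#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Full-covariance Gaussian-mixture EM. Initial means are supplied by the
// caller (seeded in R); covariance matrices start at the pooled covariance.
// A small ridge keeps covariances positive definite on degenerate clusters.
// [[Rcpp::export]]
List cpp_gmm_em(const arma::mat& X, const arma::mat& means0, int max_iter,
                double tol, double reg) {
  const int n = X.n_rows, d = X.n_cols, K = means0.n_rows;
  arma::mat means = means0;
  arma::vec weights(K, arma::fill::value(1.0 / K));
  arma::cube covs(d, d, K);
  arma::mat pooled = arma::cov(X, 1);
  pooled.diag() += reg;
  for (int k = 0; k < K; ++k) covs.slice(k) = pooled;

  arma::mat logp(n, K);
  double loglik = -arma::datum::inf;
  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step: log responsibilities via Cholesky
    for (int k = 0; k < K; ++k) {
      arma::mat L;
      if (!arma::chol(L, covs.slice(k), "lower")) {
        covs.slice(k).diag() += 10 * reg;
        arma::chol(L, covs.slice(k), "lower");
      }
      const double logdet = 2.0 * arma::accu(arma::log(L.diag()));
      arma::mat Xc = X.each_row() - means.row(k);
      arma::mat sol = arma::solve(arma::trimatl(L), Xc.t());
      arma::vec quad = arma::sum(arma::square(sol), 0).t();
      logp.col(k) = std::log(weights(k)) -
        0.5 * (d * std::log(2.0 * arma::datum::pi) + logdet) - 0.5 * quad;
    }
    arma::vec m = arma::max(logp, 1);
    arma::mat resp = arma::exp(logp.each_col() - m);
    arma::vec rs = arma::sum(resp, 1);
    const double ll = arma::accu(arma::log(rs) + m);
    resp.each_col() /= rs;

    // M-step
    arma::rowvec nk = arma::sum(resp, 0);
    for (int k = 0; k < K; ++k) {
      const double w = std::max(nk(k), 1e-10);
      means.row(k) = resp.col(k).t() * X / w;
      arma::mat Xc = X.each_row() - means.row(k);
      arma::mat S = Xc.t() * (Xc.each_col() % resp.col(k)) / w;
      S.diag() += reg;
      covs.slice(k) = S;
      weights(k) = w / n;
    }
    if (std::abs(ll - loglik) < tol * std::abs(ll)) { loglik = ll; break; }
    loglik = ll;
  }

  // final responsibilities at converged parameters
  for (int k = 0; k < K; ++k) {
    arma::mat L;
    arma::chol(L, covs.slice(k), "lower");
    const double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat Xc = X.each_row() - means.row(k);
    arma::mat sol = arma::solve(arma::trimatl(L), Xc.t());
    arma::vec quad = arma::sum(arma::square(sol), 0).t();
    logp.col(k) = std::log(weights(k)) -
      0.5 * (d * std::log(2.0 * arma::datum::pi) + logdet) - 0.5 * quad;
  }
  arma::vec m = arma::max(logp, 1);
  arma::mat resp = arma::exp(logp.each_col() - m);
  arma::vec rs = arma::sum(resp, 1);
  const double ll = arma::accu(arma::log(rs) + m);
  resp.each_col() /= rs;

  return List::create(_["loglik"] = ll, _["weights"] = weights,
                      _["means"] = means, _["covs"] = covs,
                      _["resp"] = resp);
}
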