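// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Batch EM for a full-covariance Gaussian mixture, from initial
// responsibilities. Uses the sufficient-statistics formulation so both the
// M-step covariances and the E-step Mahalanobis terms reduce to single
// matrix products against the precomputed monomial matrix P (columns
// x_a * x_b for a <= b); with z-scored features the moment form
// S = E[xx'] - mu mu' is numerically safe. Degenerate (near-empty)
// components are re-seeded at the worst-explained points; convergence is on
// the relative log-likelihood change. Deterministic: no RNG here.
// [[Rcpp::export]]
List gmm_em_cpp(const arma::mat &X, arma::mat resp, int max_iter, double tol,
                double reg) {
  const arma::uword n = X.n_rows, d = X.n_cols, k = resp.n_cols;
  const arma::uword np = d * (d + 1) / 2;
  double ll_old = -arma::datum::inf, ll = ll_old;

  // monomial columns x_a * x_b, a <= b (constant across iterations)
  arma::mat P(n, np);
  {
    arma::uword c = 0;
    for (arma::uword a = 0; a < d; ++a)
      for (arma::uword b = a; b < d; ++b, ++c)
        P.col(c) = X.col(a) % X.col(b);
  }

  arma::mat means(k, d, arma::fill::zeros);
  arma::vec weights(k, arma::fill::zeros), logdet(k, arma::fill::zeros);
  arma::cube covs(d, d, k, arma::fill::zeros);
  arma::mat Bmu(d, k), VB(np, k);
  arma::rowvec adj(k);
  const double minNk = std::max((double)d + 1.0, 1e-6 * (double)n);
  const double dl2pi = (double)d * std::log(2.0 * M_PI);
  int iter = 0, n_reseed = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    arma::rowvec Nk = arma::sum(resp, 0);
    arma::uvec empty = arma::find(Nk.t() < minNk);
    if (empty.n_elem > 0) {
      n_reseed += (int)empty.n_elem;
      arma::vec fitq = arma::max(resp, 1);
      arma::uvec ord = arma::sort_index(fitq);
      for (arma::uword e = 0; e < empty.n_elem; ++e) {
        const arma::uword row = ord(e);
        resp.row(row).zeros();
        resp(row, empty(e)) = 1.0;
      }
      Nk = arma::sum(resp, 0);
    }
    weights = Nk.t() / (double)n;
    means = resp.t() * X;            // k x d (scaled below)
    means.each_col() /= Nk.t();
    arma::mat M2 = P.t() * resp;     // np x k second moments (unnormalized)

    for (arma::uword j = 0; j < k; ++j) {
      arma::mat S(d, d);
      arma::uword c = 0;
      for (arma::uword a = 0; a < d; ++a)
        for (arma::uword b = a; b < d; ++b, ++c) {
          const double v = M2(c, j) / Nk(j) - means(j, a) * means(j, b);
          S(a, b) = v;
          S(b, a) = v;
        }
      S.diag() += reg;
      arma::mat R;
      if (!arma::chol(R, S)) {
        S.diag() += 1e-4;
        arma::chol(R, S);
      }
      covs.slice(j) = S;
      logdet(j) = 2.0 * arma::accu(arma::log(R.diag()));
      arma::mat Rinv = arma::inv(arma::trimatu(R));
      arma::mat B = Rinv * Rinv.t();           // precision matrix
      arma::vec mu = means.row(j).t();
      arma::vec bj = B * mu;
      Bmu.col(j) = bj;
      c = 0;
      for (arma::uword a = 0; a < d; ++a)
        for (arma::uword b = a; b < d; ++b, ++c)
          VB(c, j) = (a == b) ? B(a, a) : 2.0 * B(a, b);
      adj(j) = std::log(weights(j)) -
        0.5 * (dl2pi + logdet(j) + arma::dot(mu, bj));
    }

    // E step: logdens = adj + x'B mu - 0.5 x'B x, all components at once
    arma::mat logdens = X * Bmu;               // n x k cross terms
    logdens -= 0.5 * (P * VB);
    logdens.each_row() += adj;

    arma::vec m = arma::max(logdens, 1);
    logdens.each_col() -= m;
    logdens = arma::exp(logdens);
    arma::vec rs = arma::sum(logdens, 1);
    ll = arma::accu(m + arma::log(rs));
    resp = logdens.each_col() / rs;
    if (std::isfinite(ll_old) && std::abs(ll - ll_old) <= tol * std::abs(ll)) {
      ll_old = ll;
      break;
    }
    ll_old = ll;
  }

  return List::create(_["weights"] = weights, _["means"] = means,
                      _["covariances"] = covs, _["logdet"] = logdet,
                      _["loglik"] = ll_old, _["resp"] = resp,
                      _["n_iter"] = std::min(iter, max_iter),
                      _["n_reseed"] = n_reseed);
}
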