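#include <Rcpp.h>
using namespace Rcpp;

// BayesB single-site Gibbs sampler.
//
// Model: y = mu + sum_j x_j beta_j delta_j + e,
//   delta_j ~ Bernoulli(1 - pi0)                    (point mass at zero)
//   beta_j | sigma2_j ~ N(0, sigma2_j)
//   sigma2_j ~ scaled-inv-chi2(nu, s2)              (t-slab after integration)
//   e ~ N(0, sigma2_e I), sigma2_e ~ scaled-inv-chi2(nu_e, se2)
//
// delta_j is sampled with beta_j integrated out given sigma2_j; sigma2_j is
// refreshed from its full conditional (prior draw when delta_j = 0). All
// randomness comes from R's RNG, so set.seed() makes the chain reproducible.
// [[Rcpp::export]]
List bayesb_gibbs(NumericMatrix X, NumericVector y, double pi0, double nu,
                  double s2, double nu_e, double se2,
                  int n_iter, int burnin, int thin) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double ybar = mean(y);
  double mu = ybar;
  std::vector<double> beta(p, 0.0), sigma2_j(p, s2);
  std::vector<int> delta(p, 0);
  double sigma2_e = 0.0;
  for (int i = 0; i < n; ++i) sigma2_e += (y[i] - ybar) * (y[i] - ybar);
  sigma2_e = std::max(1e-8, sigma2_e / std::max(1, n - 1) * 0.5);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_sum(p, 0.0), pip_sum(p, 0.0);
  double mu_sum = 0.0;
  int n_keep = 0;
  std::vector<double> trace_s2e, trace_mu;
  const double log_prior_odds =
      (pi0 <= 0.0) ? R_PosInf : (pi0 >= 1.0 ? R_NegInf
                                            : std::log((1.0 - pi0) / pi0));

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += e[i] + mu;
    double mu_new = R::rnorm(rsum / n, std::sqrt(sigma2_e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { delta[j] = 0; beta[j] = 0.0; continue; }
      if (delta[j]) {  // add current contribution back into the residual
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * beta[j];
      }
      double rx = 0.0;
      for (int i = 0; i < n; ++i) rx += X(i, j) * e[i];
      int d_new = 0;
      if (pi0 <= 0.0) d_new = 1;
      else if (pi0 < 1.0) {
        double v = xtx[j] * sigma2_j[j] + sigma2_e;
        double log_lr = 0.5 * rx * rx * sigma2_j[j] / (sigma2_e * v)
                        - 0.5 * std::log(v / sigma2_e);
        double z = log_lr + log_prior_odds;
        double p1 = 1.0 / (1.0 + std::exp(-z));
        d_new = (R::unif_rand() < p1) ? 1 : 0;
      }
      if (d_new) {
        double v = xtx[j] * sigma2_j[j] + sigma2_e;
        double post_mean = rx * sigma2_j[j] / v;
        double post_var = sigma2_j[j] * sigma2_e / v;
        beta[j] = R::rnorm(post_mean, std::sqrt(post_var));
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * beta[j];
      } else {
        beta[j] = 0.0;
      }
      delta[j] = d_new;
      // marker-specific variance: posterior when in, prior refresh when out
      if (d_new) {
        sigma2_j[j] = (nu * s2 + beta[j] * beta[j]) / R::rchisq(nu + 1.0);
      } else {
        sigma2_j[j] = nu * s2 / R::rchisq(nu);
      }
    }

    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += e[i] * e[i];
    sigma2_e = (nu_e * se2 + rss) / R::rchisq(nu_e + n);

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++n_keep;
      mu_sum += mu;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        pip_sum[j] += delta[j];
      }
      trace_s2e.push_back(sigma2_e);
      trace_mu.push_back(mu);
    }
  }
  NumericVector bmean(p), pip(p);
  for (int j = 0; j < p; ++j) {
    bmean[j] = beta_sum[j] / n_keep;
    pip[j] = pip_sum[j] / n_keep;
  }
  return List::create(_["mu"] = mu_sum / n_keep, _["beta"] = bmean,
                      _["pip"] = pip, _["n_samples"] = n_keep,
                      _["trace_sigma2_e"] = NumericVector(trace_s2e.begin(), trace_s2e.end()),
                      _["trace_mu"] = NumericVector(trace_mu.begin(), trace_mu.end()));
}
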