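#include <Rcpp.h>
using namespace Rcpp;

// BayesCpi Gibbs sampler: y = mu + sum_j x_j beta_j delta_j + e,
// beta_j ~ N(0, sigma_b2), delta_j ~ Bern(1 - pi),
// sigma_b2 / sigma_e2 ~ scaled-inverse-chi-square(df, scale),
// pi ~ Beta(1, 1) updated from the inclusion count each sweep.
// The marker loop marginalizes beta_j when sampling delta_j:
//   P(delta=1)/P(delta=0) =
//     (1-pi)/pi * sqrt(sigma_e2 / (sigma_b2 * c)) * exp(rhs^2 / (2 sigma_e2 c))
// with c = x'x + sigma_e2 / sigma_b2 and rhs = x_j' e  (e excluding j).
// Uses R's RNG so runs are reproducible via set.seed() on the R side.

// [[Rcpp::export]]
List bayescpi_gibbs_cpp(NumericMatrix X, NumericVector y,
                        int chain_length, int burnin,
                        double pi_init, double scale_b, double scale_e,
                        double df_prior, bool update_pi, bool update_sigma,
                        double sigma_b2_init, double sigma_e2_init) {
  const int n = X.nrow();
  const int M = X.ncol();
  if (burnin >= chain_length)
    stop("burnin must be smaller than chain_length");

  std::vector<double> xtx(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    const double *xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  std::vector<double> beta(M, 0.0);
  std::vector<int> delta(M, 0);
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double sigma_b2 = sigma_b2_init;
  double sigma_e2 = sigma_e2_init;
  double pi = pi_init;

  const int n_keep = chain_length - burnin;
  NumericVector freq(M, 0.0), beta_mean(M, 0.0), marker_var(M, 0.0);
  NumericVector pi_chain(chain_length), sb2_chain(chain_length),
      se2_chain(chain_length), h2_chain(chain_length);
  IntegerVector m_chain(chain_length);
  long long total_incl = 0;

  RNGScope scope;

  for (int it = 0; it < chain_length; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + norm_rand() * std::sqrt(sigma_e2 / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= shift;
    mu = mu_new;

    int m_incl = 0;
    double sum_b2 = 0.0;
    const double log_prior_odds = std::log((1.0 - pi) / pi);
    for (int j = 0; j < M; ++j) {
      const double *xj = &X(0, j);
      if (delta[j]) {           // remove current contribution
        const double bj = beta[j];
        for (int i = 0; i < n; ++i) e[i] += xj[i] * bj;
      }
      if (xtx[j] <= 0.0) { delta[j] = 0; beta[j] = 0.0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      const double c = xtx[j] + sigma_e2 / sigma_b2;
      const double logodds = log_prior_odds +
        0.5 * std::log(sigma_e2 / (sigma_b2 * c)) +
        0.5 * rhs * rhs / (sigma_e2 * c);
      const double p1 = 1.0 / (1.0 + std::exp(-logodds));
      if (unif_rand() < p1) {
        delta[j] = 1;
        const double bj = rhs / c + norm_rand() * std::sqrt(sigma_e2 / c);
        beta[j] = bj;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * bj;
        ++m_incl;
        sum_b2 += bj * bj;
      } else {
        delta[j] = 0;
        beta[j] = 0.0;
      }
    }

    if (update_sigma) {
      sigma_b2 = (sum_b2 + df_prior * scale_b) /
        R::rchisq(df_prior + m_incl);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = (sse + df_prior * scale_e) / R::rchisq(df_prior + n);
      if (!R_finite(sigma_e2) || sigma_e2 <= 0.0)
        stop("divergent residual variance at iteration %d", it + 1);
    }
    if (update_pi)
      pi = R::rbeta((double)(M - m_incl) + 1.0, (double)m_incl + 1.0);

    // realized genetic variance of g = y - mu - e
    double gbar = 0.0;
    std::vector<double> g(n);
    for (int i = 0; i < n; ++i) { g[i] = y[i] - mu - e[i]; gbar += g[i]; }
    gbar /= n;
    double var_g = 0.0;
    for (int i = 0; i < n; ++i) var_g += (g[i] - gbar) * (g[i] - gbar);
    var_g /= (n - 1);

    pi_chain[it] = pi;
    sb2_chain[it] = sigma_b2;
    se2_chain[it] = sigma_e2;
    m_chain[it] = m_incl;
    h2_chain[it] = var_g / (var_g + sigma_e2);

    if (it >= burnin) {
      for (int j = 0; j < M; ++j) {
        if (delta[j]) {
          freq[j] += 1.0;
          total_incl += 1;
        }
        beta_mean[j] += beta[j];
        marker_var[j] += beta[j] * beta[j] * xtx[j] / (n - 1);
      }
    }
  }

  for (int j = 0; j < M; ++j) {
    freq[j] /= n_keep;
    beta_mean[j] /= n_keep;
    marker_var[j] /= n_keep;
  }

  return List::create(
      _["model_frequency"] = freq,
      _["beta_mean"] = beta_mean,
      _["marker_variance"] = marker_var,
      _["pi_chain"] = pi_chain,
      _["sigma_b2_chain"] = sb2_chain,
      _["sigma_e2_chain"] = se2_chain,
      _["m_chain"] = m_chain,
      _["h2_chain"] = h2_chain,
      _["total_inclusions"] = (double)total_incl);
}
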