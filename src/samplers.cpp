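#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs sampler with G >= 1 gene groups (single-group =
// BayesC, two groups = the GO-partitioned variant). Indicator and effect
// are sampled jointly from their exact conditional per coordinate; pi and
// the variances from beta / scaled-inverse-chi-square conditionals.
// Uses R's RNG so set.seed() on the R side controls the chain.
// [[Rcpp::export]]
List bayesc_gibbs(const NumericMatrix& X, const NumericVector& y,
                  const IntegerVector& grp, const int n_groups,
                  const int n_iter, const int burn_in, const int thin,
                  NumericVector pi, NumericVector sigma_b2, double sigma_e2,
                  const NumericVector& Sb, const double df_b,
                  const double Se, const double df_e,
                  const NumericVector& prior_a, const NumericVector& prior_b,
                  const bool update_pi, const bool update_sb,
                  const bool update_se) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> beta(m, 0.0), xx(m);
  std::vector<int> delta(m, 0), msize(n_groups, 0);
  NumericVector e = clone(y);
  for (int j = 0; j < m; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s;
    msize[grp[j]]++;
  }
  const int n_ret = (n_iter - burn_in) / thin;
  NumericVector pip(m, 0.0), beta_mean(m, 0.0);
  // draws: sigma_e2, then per group sigma_b2, pi, n_active
  NumericMatrix draws(n_ret, 1 + 3 * n_groups);
  int ret = 0;
  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      const double* xj = &X(0, j);
      const int g = grp[j];
      double rhs = xx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      const double lam = sigma_e2 / sigma_b2[g];
      const double c = xx[j] + lam;
      const double logBF = 0.5 * (std::log(lam) - std::log(c)) +
        rhs * rhs / (2.0 * sigma_e2 * c);
      const double logodds = std::log(pi[g] / (1.0 - pi[g])) + logBF;
      const double p1 = 1.0 / (1.0 + std::exp(-logodds));
      const double old = beta[j];
      double bj = 0.0;
      if (unif_rand() < p1) {
        bj = rhs / c + std::sqrt(sigma_e2 / c) * norm_rand();
        delta[j] = 1;
      } else {
        delta[j] = 0;
      }
      beta[j] = bj;
      if (bj != old) {
        const double diff = old - bj;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * diff;
      }
    }
    // refresh residual periodically to cancel accumulated rounding drift
    if (it % 200 == 0) {
      for (int i = 0; i < n; ++i) e[i] = y[i];
      for (int j = 0; j < m; ++j) {
        if (beta[j] != 0.0) {
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) e[i] -= xj[i] * beta[j];
        }
      }
    }
    std::vector<double> ssb(n_groups, 0.0);
    std::vector<int> kact(n_groups, 0);
    for (int j = 0; j < m; ++j) {
      if (delta[j]) { kact[grp[j]]++; ssb[grp[j]] += beta[j] * beta[j]; }
    }
    for (int g = 0; g < n_groups; ++g) {
      if (update_pi) {
        double p = R::rbeta(prior_a[g] + kact[g],
                            prior_b[g] + msize[g] - kact[g]);
        pi[g] = std::min(1.0 - 1e-8, std::max(1e-8, p));
      }
      if (update_sb)
        sigma_b2[g] = (ssb[g] + df_b * Sb[g]) / R::rchisq(df_b + kact[g]);
    }
    if (update_se) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = (sse + df_e * Se) / R::rchisq(df_e + n);
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && ret < n_ret) {
      for (int j = 0; j < m; ++j) {
        pip[j] += delta[j];
        beta_mean[j] += beta[j];
      }
      draws(ret, 0) = sigma_e2;
      for (int g = 0; g < n_groups; ++g) {
        draws(ret, 1 + g) = sigma_b2[g];
        draws(ret, 1 + n_groups + g) = pi[g];
        draws(ret, 1 + 2 * n_groups + g) = kact[g];
      }
      ret++;
    }
  }
  for (int j = 0; j < m; ++j) { pip[j] /= ret; beta_mean[j] /= ret; }
  return List::create(_["pip"] = pip, _["beta_mean"] = beta_mean,
                      _["draws"] = draws, _["retained"] = ret);
}

// One coordinate-ascent sweep of the fully-factorized variational
// approximation for spike-and-slab regression. alpha, mu, s2 and the fitted
// vector Xr (= X (alpha*mu)) are updated in place.
// [[Rcpp::export]]
void varbvs_sweep(const NumericMatrix& X, const NumericVector& xx,
                  const NumericVector& xty, NumericVector alpha,
                  NumericVector mu, NumericVector s2, NumericVector Xr,
                  const double sigma_e2, const double sigma_b2,
                  const double logit_pi) {
  const int n = X.nrow(), m = X.ncol();
  for (int j = 0; j < m; ++j) {
    const double* xj = &X(0, j);
    const double s2j = sigma_e2 / (xx[j] + sigma_e2 / sigma_b2);
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * Xr[i];
    const double r = xty[j] - dot + xx[j] * alpha[j] * mu[j];
    const double muj = s2j * r / sigma_e2;
    const double lo = logit_pi + 0.5 * std::log(s2j / sigma_b2) +
      muj * muj / (2.0 * s2j);
    const double aj = 1.0 / (1.0 + std::exp(-lo));
    const double diff = aj * muj - alpha[j] * mu[j];
    if (diff != 0.0)
      for (int i = 0; i < n; ++i) Xr[i] += xj[i] * diff;
    alpha[j] = aj; mu[j] = muj; s2[j] = s2j;
  }
}

// One coordinate-ascent sweep for the mixture-of-normals prior (first grid
// entry is the point mass at zero). Per-coordinate responsibilities phi and
// component means mu (m x K), the posterior-mean vector betabar and the
// residual resid = y - X betabar are updated in place.
// [[Rcpp::export]]
void mrash_sweep(const NumericMatrix& X, const NumericVector& xx,
                 const NumericVector& sigma_grid, const NumericVector& log_pi,
                 NumericVector betabar, NumericVector resid,
                 NumericMatrix phi, NumericMatrix mu,
                 const double sigma_e2) {
  const int n = X.nrow(), m = X.ncol(), K = sigma_grid.size();
  std::vector<double> lw(K), mk(K), sk(K);
  for (int j = 0; j < m; ++j) {
    const double* xj = &X(0, j);
    double r = xx[j] * betabar[j];
    for (int i = 0; i < n; ++i) r += xj[i] * resid[i];
    double lmax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      if (sigma_grid[k] <= 0.0) {
        lw[k] = log_pi[k]; mk[k] = 0.0; sk[k] = 0.0;
      } else {
        const double s2k = sigma_e2 / (xx[j] + sigma_e2 / sigma_grid[k]);
        const double muk = s2k * r / sigma_e2;
        lw[k] = log_pi[k] + 0.5 * std::log(s2k / sigma_grid[k]) +
          muk * muk / (2.0 * s2k);
        mk[k] = muk; sk[k] = s2k;
      }
      if (lw[k] > lmax) lmax = lw[k];
    }
    double tot = 0.0, bnew = 0.0;
    for (int k = 0; k < K; ++k) {
      lw[k] = std::exp(lw[k] - lmax);
      tot += lw[k];
    }
    for (int k = 0; k < K; ++k) {
      const double p = lw[k] / tot;
      phi(j, k) = p; mu(j, k) = mk[k];
      bnew += p * mk[k];
    }
    const double diff = betabar[j] - bnew;
    if (diff != 0.0)
      for (int i = 0; i < n; ++i) resid[i] += xj[i] * diff;
    betabar[j] = bnew;
  }
}
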