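// Single-site Gibbs samplers for whole-genome regression:
//   bayesb_sampler : spike-and-slab marker effects (point mass at zero with
//                    prior probability pi, else normal with per-marker
//                    variance under a scaled-inverse-chi-square prior)
//   blasso_sampler : double-exponential (Laplace) marker effects via the
//                    scale-mixture-of-normals representation (Park & Casella)
// Both use R's RNG so set.seed() on the R side gives bit-reproducible chains.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inverse-chi-square draw: (df * scale + ss) / chisq(df + n)
static inline double rscinv_chisq(double df, double num) {
  return num / R::rchisq(df);
}

// inverse-Gaussian draw (Michael, Schucany & Haas)
static inline double rinvgauss(double mu, double lambda) {
  double z = R::rnorm(0.0, 1.0);
  double y = z * z;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (R::runif(0.0, 1.0) <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".bayesb_sampler")]]
List bayesb_sampler(NumericVector y, NumericMatrix X, int niter, int burnin,
                    int thin, double pi_zero, double df_beta, double S_beta,
                    double df_e, double S_e, bool sample_pi) {
  int n = y.size(), m = X.ncol();
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  NumericVector beta(m, 0.0), sigma2_j(m, S_beta);
  LogicalVector incl(m, false);
  NumericVector e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2e = S_e * df_e / (df_e - 2.0);
  double pi_cur = pi_zero;

  double mu_sum = 0.0, s2e_sum = 0.0, pi_sum = 0.0;
  NumericVector beta_sum(m, 0.0), incl_sum(m, 0.0);
  int nsave = 0;

  for (int it = 0; it < niter; ++it) {
    int k_in = 0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];
      // marginal likelihood of the sufficient statistic under in/out
      double v0 = xtx[j] * sigma2e;
      double v1 = v0 + xtx[j] * xtx[j] * sigma2_j[j];
      double l1 = -0.5 * log(v1) - 0.5 * rhs * rhs / v1 + log(1.0 - pi_cur);
      double l0 = -0.5 * log(v0) - 0.5 * rhs * rhs / v0 + log(pi_cur);
      double p_in = 1.0 / (1.0 + exp(l0 - l1));
      double beta_old = beta[j];
      if (R::runif(0.0, 1.0) < p_in) {
        double prec = xtx[j] + sigma2e / sigma2_j[j];
        double bnew = R::rnorm(rhs / prec, sqrt(sigma2e / prec));
        beta[j] = bnew;
        incl[j] = true;
        ++k_in;
        sigma2_j[j] = rscinv_chisq(df_beta + 1.0,
                                   df_beta * S_beta + bnew * bnew);
      } else {
        beta[j] = 0.0;
        incl[j] = false;
        sigma2_j[j] = rscinv_chisq(df_beta, df_beta * S_beta);
      }
      double diff = beta_old - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
      }
    }
    // intercept
    double ebar = mean(e);
    double mu_new = R::rnorm(mu + ebar, sqrt(sigma2e / n));
    double dmu = mu_new - mu;
    mu = mu_new;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = rscinv_chisq(df_e + n, df_e * S_e + sse);
    if (sigma2e < 1e-12) sigma2e = 1e-12;
    // optional Beta(1,1) update of the exclusion probability
    if (sample_pi) {
      pi_cur = R::rbeta(1.0 + (m - k_in), 1.0 + k_in);
      if (pi_cur > 0.999) pi_cur = 0.999;
      if (pi_cur < 0.001) pi_cur = 0.001;
    }
    if (!R_finite(mu) || !R_finite(sigma2e)) stop("divergent chain");
    if (it >= burnin && (it - burnin) % thin == 0) {
      ++nsave;
      mu_sum += mu;
      s2e_sum += sigma2e;
      pi_sum += pi_cur;
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        if (incl[j]) incl_sum[j] += 1.0;
      }
    }
  }
  return List::create(
    _["mu"] = mu_sum / nsave,
    _["beta"] = beta_sum / (double)nsave,
    _["incl_prob"] = incl_sum / (double)nsave,
    _["sigma2e"] = s2e_sum / nsave,
    _["pi_zero"] = pi_sum / nsave,
    _["nsave"] = nsave);
}

// [[Rcpp::export(name = ".blasso_sampler")]]
List blasso_sampler(NumericVector y, NumericMatrix X, int niter, int burnin,
                    int thin, double lambda2_init, double shape_lambda,
                    double rate_lambda, double df_e, double S_e) {
  int n = y.size(), m = X.ncol();
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  NumericVector beta(m, 0.0), tau2(m, 1.0);
  NumericVector e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2e = S_e * df_e / (df_e - 2.0);
  double lambda2 = lambda2_init;

  double mu_sum = 0.0, s2e_sum = 0.0, l2_sum = 0.0;
  NumericVector beta_sum(m, 0.0);
  int nsave = 0;

  for (int it = 0; it < niter; ++it) {
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];
      double prec = xtx[j] + 1.0 / tau2[j];
      double bnew = R::rnorm(rhs / prec, sqrt(sigma2e / prec));
      double diff = beta[j] - bnew;
      beta[j] = bnew;
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
      }
      // 1/tau2 | beta ~ InvGauss(sqrt(lambda2 sigma2e / beta^2), lambda2)
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-12) b2 = 1e-12;
      double invtau2 = rinvgauss(sqrt(lambda2 * sigma2e / b2), lambda2);
      if (invtau2 < 1e-12) invtau2 = 1e-12;
      tau2[j] = 1.0 / invtau2;
    }
    double ebar = mean(e);
    double mu_new = R::rnorm(mu + ebar, sqrt(sigma2e / n));
    double dmu = mu_new - mu;
    mu = mu_new;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    double sse = 0.0, sbt = 0.0, stau = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    for (int j = 0; j < m; ++j) {
      sbt += beta[j] * beta[j] / tau2[j];
      stau += tau2[j];
    }
    sigma2e = rscinv_chisq(df_e + n + m, df_e * S_e + sse + sbt);
    if (sigma2e < 1e-12) sigma2e = 1e-12;
    lambda2 = R::rgamma(shape_lambda + m, 1.0 / (rate_lambda + stau / 2.0));
    if (!R_finite(mu) || !R_finite(sigma2e) || !R_finite(lambda2)) {
      stop("divergent chain");
    }
    if (it >= burnin && (it - burnin) % thin == 0) {
      ++nsave;
      mu_sum += mu;
      s2e_sum += sigma2e;
      l2_sum += lambda2;
      for (int j = 0; j < m; ++j) beta_sum[j] += beta[j];
    }
  }
  return List::create(
    _["mu"] = mu_sum / nsave,
    _["beta"] = beta_sum / (double)nsave,
    _["sigma2e"] = s2e_sum / nsave,
    _["lambda2"] = l2_sum / nsave,
    _["nsave"] = nsave);
}
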