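// Core numerical layer: model log-likelihoods, log-priors and an adaptive
// random-walk Metropolis sampler.  Everything runs on the unconstrained
// parameter scale; the R side owns the parameter layout (see param_table()).
//
// Integer codes (kept in sync with R/inference.R):
//   data_kind:        0 count, 1 frequency
//   family:           0 poisson, 1 negbinom, 2 zi_negbinom, 3 zi_gamma
//   effect_structure: 0 none, 1 mean_only, 2 mean_and_zi
//   effect_type:      0 fixed_categorical, 1 fixed_linear,
//                     2 random_intercept, 3 random_slope
//
// Parameter roles (per coordinate of theta):
//   0 normal(prior_mean, prior_sd)
//   1 log of a half-normal scale: sigma = exp(theta), p(sigma) ~ HN(prior_sd),
//     with the log-transform Jacobian included
//   2 latent random effect: N(0, sigma^2), sigma taken from coordinate
//     `i_logsigma`

#include <Rcpp.h>
using namespace Rcpp;

struct ModelCode {
  int data_kind, family, effect_structure, effect_type;
  // indices into theta, -1 if absent (0-based)
  int i_loglam, i_beta, i_logsigma, i_latent0, n_latent;
  int i_logk, i_logitpzi, i_logshape, i_g, i_betazi;
  int p0_literal; // 0: p0 decreasing in mu (default), 1: literal increasing form
};

static ModelCode unpack_model(const IntegerVector& mc) {
  ModelCode m;
  m.data_kind = mc["data_kind"];
  m.family = mc["family"];
  m.effect_structure = mc["effect_structure"];
  m.effect_type = mc["effect_type"];
  m.i_loglam = mc["i_loglam"];
  m.i_beta = mc["i_beta"];
  m.i_logsigma = mc["i_logsigma"];
  m.i_latent0 = mc["i_latent0"];
  m.n_latent = mc["n_latent"];
  m.i_logk = mc["i_logk"];
  m.i_logitpzi = mc["i_logitpzi"];
  m.i_logshape = mc["i_logshape"];
  m.i_g = mc["i_g"];
  m.i_betazi = mc["i_betazi"];
  m.p0_literal = mc["p0_literal"];
  return m;
}

// log(exp(a) + exp(b)) without overflow
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// per-row covariate contribution to the log-rate linear predictor
static inline double eff_term(const ModelCode& m, const double* th,
                              double x, int cat) {
  switch (m.effect_type) {
  case 0: // fixed categorical
  case 1: // fixed linear
    return th[m.i_beta] * x;
  case 2: // random intercept
    return th[m.i_latent0 + cat];
  case 3: // random slope
    return th[m.i_latent0 + cat] * x;
  }
  return 0.0;
}

static double loglik_one(const ModelCode& m, const double* th,
                         double y, double flowers, double x, int cat) {
  double eta = th[m.i_loglam];
  double et = 0.0;
  if (m.effect_structure >= 1) {
    et = eff_term(m, th, x, cat);
    eta += et;
  }
  if (m.data_kind == 0) { // counts, log(flowers) offset
    double mu = flowers * std::exp(eta);
    double base;
    switch (m.family) {
    case 0:
      return R::dpois(y, mu, 1);
    case 1:
      return R::dnbinom_mu(y, std::exp(th[m.i_logk]), mu, 1);
    case 2: { // zero-inflated NB, covariate-free inflation probability
      double pzi = R::plogis(th[m.i_logitpzi], 0.0, 1.0, 1, 0);
      base = R::dnbinom_mu(y, std::exp(th[m.i_logk]), mu, 1);
      if (y == 0.0)
        return logadd(std::log(pzi), std::log1p(-pzi) + base);
      return std::log1p(-pzi) + base;
    }
    }
  } else { // frequency, zero-inflated gamma on mu = exp(eta)
    double h = th[m.i_g] + eta;             // logit-scale driver g + log(mu)
    double lp0 = m.p0_literal ? h : -h;     // logit p0
    if (m.effect_structure == 2) {
      // direct covariate effect on the zero-inflation: for fixed effects the
      // raw covariate, for random effects the category's latent term
      double u = (m.effect_type <= 1) ? x : et;
      lp0 += th[m.i_betazi] * u;
    }
    double lg_p0 = -std::log1p(std::exp(-lp0));      // log p0
    double lg_1mp0 = -std::log1p(std::exp(lp0));     // log(1 - p0)
    if (y == 0.0) return lg_p0;
    double shape = std::exp(th[m.i_logshape]);
    double mu = std::exp(eta);
    return lg_1mp0 + R::dgamma(y, shape, mu / shape, 1);
  }
  return R_NegInf;
}

static double loglik_all(const ModelCode& m, const double* th,
                         const NumericVector& y, const NumericVector& flowers,
                         const NumericVector& x, const IntegerVector& cat) {
  double s = 0.0;
  int n = y.size();
  for (int i = 0; i < n; ++i) {
    s += loglik_one(m, th, y[i], flowers[i], x[i], cat[i]);
    if (!std::isfinite(s)) return R_NegInf;
  }
  return s;
}

static double logprior_all(const double* th, int d,
                           const IntegerVector& role,
                           const NumericVector& pm, const NumericVector& ps,
                           int i_logsigma) {
  double s = 0.0;
  double sigma = (i_logsigma >= 0) ? std::exp(th[i_logsigma]) : NA_REAL;
  for (int j = 0; j < d; ++j) {
    switch (role[j]) {
    case 0:
      s += R::dnorm(th[j], pm[j], ps[j], 1);
      break;
    case 1: // half-normal on sigma = exp(theta), plus Jacobian
      s += M_LN2 + R::dnorm(std::exp(th[j]), 0.0, ps[j], 1) + th[j];
      break;
    case 2:
      s += R::dnorm(th[j], 0.0, sigma, 1);
      break;
    }
  }
  return s;
}

// [[Rcpp::export(name = ".cp_loglik")]]
double cp_loglik(IntegerVector model, NumericVector theta, NumericVector y,
                 NumericVector flowers, NumericVector x, IntegerVector cat) {
  ModelCode m = unpack_model(model);
  return loglik_all(m, REAL(theta), y, flowers, x, cat);
}

// [[Rcpp::export(name = ".cp_logprior")]]
double cp_logprior(NumericVector theta, IntegerVector role, NumericVector pm,
                   NumericVector ps, int i_logsigma) {
  return logprior_all(REAL(theta), theta.size(), role, pm, ps, i_logsigma);
}

// Row-wise evaluation for the importance-sampling step: returns a matrix with
// columns (log-likelihood, log-prior), one row per draw.
// [[Rcpp::export(name = ".cp_target_terms")]]
NumericMatrix cp_target_terms(IntegerVector model, NumericMatrix draws,
                              NumericVector y, NumericVector flowers,
                              NumericVector x, IntegerVector cat,
                              IntegerVector role, NumericVector pm,
                              NumericVector ps, int i_logsigma) {
  ModelCode m = unpack_model(model);
  int n = draws.nrow(), d = draws.ncol();
  NumericMatrix out(n, 2);
  std::vector<double> th(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) th[j] = draws(i, j);
    out(i, 0) = loglik_all(m, th.data(), y, flowers, x, cat);
    out(i, 1) = logprior_all(th.data(), d, role, pm, ps, i_logsigma);
  }
  return out;
}

// Adaptive random-walk Metropolis.  Joint Gaussian proposal with
// per-coordinate scales; the global step size adapts towards a 0.234
// acceptance rate in windows of 50 iterations during burn-in, and the
// per-coordinate scales track the running standard deviation of the chain.
// Adaptation is frozen after burn-in so the retained draws target the exact
// posterior.  Uses R's RNG stream (seeded from R via set.seed()).
// [[Rcpp::export(name = ".cp_mcmc_chain")]]
List cp_mcmc_chain(IntegerVector model, NumericVector theta0, NumericVector y,
                   NumericVector flowers, NumericVector x, IntegerVector cat,
                   IntegerVector role, NumericVector pm, NumericVector ps,
                   int i_logsigma, int n_iter, int n_burn, int thin) {
  ModelCode m = unpack_model(model);
  int d = theta0.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> prop(d), scale(d, 0.2);
  std::vector<double> run_mean(th), run_m2(d, 0.0);

  double lc = std::log(2.38 / std::sqrt((double)d));
  double lp = loglik_all(m, th.data(), y, flowers, x, cat) +
              logprior_all(th.data(), d, role, pm, ps, i_logsigma);
  if (!std::isfinite(lp)) stop("non-finite log-posterior at the initial value");

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, d);
  NumericVector lpost(n_keep);
  int kept = 0, acc_win = 0, acc_tot = 0, win = 0;

  for (int it = 0; it < n_iter; ++it) {
    double c = std::exp(lc);
    for (int j = 0; j < d; ++j) prop[j] = th[j] + c * scale[j] * R::norm_rand();
    double lp_new = loglik_all(m, prop.data(), y, flowers, x, cat) +
                    logprior_all(prop.data(), d, role, pm, ps, i_logsigma);
    if (std::isfinite(lp_new) && std::log(R::unif_rand()) < lp_new - lp) {
      th = prop;
      lp = lp_new;
      ++acc_win;
      if (it >= n_burn) ++acc_tot;
    } else if (it >= n_burn) {
      // counted below through acc_tot only on acceptance
    }
    // running moments for per-coordinate scales
    double w = 1.0 / (it + 2.0);
    for (int j = 0; j < d; ++j) {
      double delta = th[j] - run_mean[j];
      run_mean[j] += w * delta;
      run_m2[j] += delta * (th[j] - run_mean[j]);
    }
    ++win;
    if (it < n_burn && win == 50) {
      double ar = acc_win / 50.0;
      lc += 0.7 * (ar - 0.234);
      if (lc < -8.0) lc = -8.0;
      if (lc > 3.0) lc = 3.0;
      if (it > 100) {
        for (int j = 0; j < d; ++j) {
          double sd = std::sqrt(run_m2[j] / (it + 1.0));
          scale[j] = sd > 0.05 ? sd : 0.05;
        }
      }
      acc_win = 0;
      win = 0;
    }
    if (it >= n_burn && ((it - n_burn) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < d; ++j) draws(kept, j) = th[j];
      lpost[kept] = lp;
      ++kept;
    }
  }
  return List::create(_["draws"] = draws, _["logpost"] = lpost,
                      _["accept_rate"] = (double)acc_tot / (n_iter - n_burn));
}
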