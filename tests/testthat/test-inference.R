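test_that("log_likelihood matches hand computations and basic identities", {
  one_row <- structure(
    data.frame(flowers = 100L, category = NA_integer_, x = 0, visits = 0L),
    class = c("count_dataset", "data.frame"))
  m <- model_spec("count", "poisson", "none")
  expect_equal(log_likelihood(m, one_row, log(0.02)), -2)
  # iid rows: permutation invariance
  ds <- small_count_ds(seed = 31)
  perm <- ds[sample.int(nrow(ds)), ]
  me <- model_spec("count", "negbinom", "mean_only", "fixed_categorical")
  th <- c(log(0.02), 0.4, log(8))
  expect_equal(log_likelihood(me, ds, th), log_likelihood(me, perm, th))
  # ZINB with p_zi = 0 collapses to NB exactly
  mnb <- model_spec("count", "negbinom", "mean_only", "fixed_categorical")
  mzi <- model_spec("count", "zi_negbinom", "mean_only", "fixed_categorical")
  expect_equal(log_likelihood(mzi, ds, c(th, -Inf)),
               log_likelihood(mnb, ds, th))
  expect_error(log_likelihood(mnb, ds, th[1:2]), "length")
})

test_that("R and compiled likelihoods agree across all model structures", {
  set.seed(77)
  for (etype in c("fixed_categorical", "fixed_linear", "random_intercept",
                  "random_slope")) {
    es <- effect_spec(etype, strength = 0.5)
    n <- default_n_rows(etype)
    ds <- simulate_dataset(count_family("poisson"), es, exposure_fixture(),
                           n, seed = 17)
    fr <- to_frequency(ds)
    sets <- c(count_model_set(etype), frequency_model_set(etype))
    for (m in sets) {
      use <- if (m$data_kind == "count") ds else fr
      pt <- countpower:::param_table(m)
      md <- countpower:::model_data(m, use)
      for (rep in 1:3) {
        th <- rnorm(pt$d, 0, 0.4)
        th[1] <- log(0.02) + rnorm(1, 0, 0.3)
        a <- log_likelihood(m, use, th)
        b <- countpower:::.cp_loglik(countpower:::model_ints(m, pt), th,
                                     md$y, md$flowers, md$x, md$cat)
        expect_equal(a, b, tolerance = 1e-10)
      }
    }
  }
})

test_that("run_mcmc is deterministic and recovers a known rate", {
  ds <- structure(
    local({
      set.seed(123)
      es0 <- effect_spec("fixed_categorical", effect_present = FALSE)
      simulate_dataset(count_family("poisson"), es0, exposure_fixture(),
                       n = 1000, seed = 123)
    }),
    class = c("count_dataset", "data.frame"))
  m <- model_spec("count", "poisson", "none")
  ch1 <- run_mcmc(m, ds, n_iter = 3000, seed = 5)
  ch2 <- run_mcmc(m, ds, n_iter = 3000, seed = 5)
  expect_identical(ch1$draws, ch2$draws)
  expect_true(ch1$converged)
  lam_hat <- exp(mean(unlist(lapply(ch1$draws, function(d) d[, 1]))))
  expect_lt(abs(lam_hat - 0.02) / 0.02, 0.10)
  expect_true(all(ch1$accept_rate > 0.1 & ch1$accept_rate < 0.5))
})

test_that("NB fit on Poisson data pushes k to large values", {
  es0 <- effect_spec("fixed_categorical", effect_present = FALSE)
  ds <- simulate_dataset(count_family("poisson"), es0, exposure_fixture(),
                         n = 300, seed = 99)
  m <- model_spec("count", "negbinom", "none")
  ch <- run_mcmc(m, ds, n_iter = 4000, seed = 6)
  k_draws <- exp(unlist(lapply(ch$draws, function(d) d[, "log_k"])))
  expect_gt(quantile(k_draws, 0.05), 10)
})

test_that("posterior recovery works for every model structure", {
  # scaled-down recovery screen: one simulated dataset per generating
  # structure, posterior mean of the baseline log-rate near the truth
  set.seed(55)
  cases <- list(
    list("poisson", "fixed_categorical", "mean_only", 0.8),
    list("negbinom", "fixed_linear", "mean_only", 1.0),
    list("zi_negbinom", "fixed_categorical", "mean_only", 0.8),
    list("poisson", "random_intercept", "mean_only", 0.8),
    list("poisson", "random_slope", "mean_only", 1.0))
  for (cs in cases) {
    fam <- switch(cs[[1]], poisson = count_family("poisson"),
                  negbinom = count_family("negbinom", k = 10),
                  zi_negbinom = count_family("negbinom", k = 10))
    es <- effect_spec(cs[[2]], strength = cs[[4]])
    n <- max(default_n_rows(cs[[2]]), 100)
    n <- n - n %% 5
    ds <- simulate_dataset(fam, es, exposure_fixture(), n, seed = 71)
    m <- model_spec("count", cs[[1]], cs[[3]], cs[[2]])
    ch <- run_mcmc(m, ds, n_iter = 4000, seed = 8)
    loglam <- unlist(lapply(ch$draws, function(d) d[, 1]))
    # generous interval: small data, wide priors
    expect_lt(abs(mean(loglam) - log(0.02)), 1,
              label = paste("loglam recovery for", cs[[1]], cs[[2]]))
  }
  # frequency model recovery of the gamma expectancy on its own data
  par <- zi_gamma_params(0.05, 1.2, 1.5)
  set.seed(4)
  fr <- structure(data.frame(category = NA_integer_, x = 0,
                             freq = zi_gamma_sample(400, par)),
                  class = c("frequency_dataset", "data.frame"))
  mf <- model_spec("frequency", "zi_gamma", "none")
  ch <- run_mcmc(mf, fr, n_iter = 4000, seed = 9)
  mu_hat <- exp(mean(unlist(lapply(ch$draws, function(d) d[, 1]))))
  expect_lt(abs(mu_hat - 0.05) / 0.05, 0.25)
})

test_that("estimate_log_bml matches the conjugate oracle and scales", {
  set.seed(303)
  a <- 1.5; b <- 2
  f <- c(20, 50, 120, 7)
  y <- c(1, 0, 4, 0)
  exact <- poisson_gamma_log_marginal(y, f, a, b)
  draws <- matrix(log(rgamma(3000, a + sum(y), b + sum(f))), ncol = 1)
  lt <- function(th) {
    lam <- exp(th[, 1])
    dgamma(lam, a, b, log = TRUE) + th[, 1] +
      vapply(lam, function(l) sum(dpois(y, l * f, log = TRUE)), 0)
  }
  est <- estimate_log_bml(draws = draws, log_target = lt, n_draws = 2000,
                          seed = 1)
  expect_lt(abs(est$log_bml - exact), 3 * est$mc_se)
  expect_gt(est$ess, 50)
  # doubling the draw count shrinks mc_se by about sqrt(2)
  ses <- vapply(c(2000, 4000), function(nd) {
    mean(vapply(1:8, function(s)
      estimate_log_bml(draws = draws, log_target = lt, n_draws = nd,
                       seed = s)$mc_se, 0))
  }, 0)
  expect_gt(ses[1] / ses[2], 1.15)
  expect_lt(ses[1] / ses[2], 1.75)
  # adding a constant to the log-target shifts log_bml by that constant
  e1 <- estimate_log_bml(draws = draws, log_target = lt, n_draws = 500,
                         seed = 11)
  e2 <- estimate_log_bml(draws = draws,
                         log_target = function(th) lt(th) + 7.3,
                         n_draws = 500, seed = 11)
  expect_equal(e2$log_bml - e1$log_bml, 7.3, tolerance = 1e-10)
})

test_that("estimate_log_bml flags degenerate importance weights", {
  set.seed(8)
  draws <- matrix(rnorm(2000, 0, 0.05), ncol = 1)
  # target much wider than the importance density: weights degenerate
  lt <- function(th) dnorm(th[, 1], 0, 50, log = TRUE)
  expect_warning(
    est <- estimate_log_bml(draws = draws, log_target = lt, n_draws = 500,
                            seed = 2),
    "degenerate")
  expect_true(est$degenerate)
})

test_that("posterior_model_probs is a stable softmax", {
  expect_equal(posterior_model_probs(c(-1000, -1000, -1000)), rep(1 / 3, 3))
  p <- posterior_model_probs(c(log(3), 0))
  expect_equal(p, c(0.75, 0.25))
  p <- posterior_model_probs(c(0, 0), prior_probs = c(1, 0))
  expect_equal(p, c(1, 0))
  # equivariant under permutation of model order
  lb <- c(-3, -1, -2.5)
  expect_equal(posterior_model_probs(lb)[c(2, 1, 3)],
               posterior_model_probs(lb[c(2, 1, 3)]))
  expect_equal(sum(posterior_model_probs(c(-1e8, 0, 1e8))), 1)
  expect_error(posterior_model_probs(numeric(0)), "empty")
  expect_error(posterior_model_probs(c(0, 0), prior_probs = c(0.7, 0.7)),
               "sum to 1")
})

test_that("detect_effect applies the strict Bayes-factor rule", {
  lb <- c(n1 = -10, e1 = -10)
  is_eff <- c(FALSE, TRUE)
  expect_false(detect_effect(lb, is_eff, 1)$found) # tie -> no effect
  expect_equal(detect_effect(lb, is_eff, 1)$score, 0)
  # shift invariance of the score
  lb2 <- c(-3, -1, -7, -2)
  ie <- c(FALSE, TRUE, FALSE, TRUE)
  expect_equal(detect_effect(lb2, ie)$score,
               detect_effect(lb2 + 100, ie)$score)
  # threshold limits
  expect_false(detect_effect(lb2, ie, threshold = 1e12)$found)
  expect_true(detect_effect(lb2, ie, threshold = 1e-12)$found)
  expect_error(detect_effect(lb2, rep(TRUE, 4)), "no-effect")
})

test_that("model sets have the study's structure", {
  cs <- count_model_set("fixed_linear")
  expect_length(cs, 6)
  expect_equal(sum(attr(cs, "is_effect")), 3)
  expect_true(all(vapply(cs, function(m) m$data_kind == "count", TRUE)))
  fs <- frequency_model_set("fixed_linear")
  expect_length(fs, 3)
  expect_equal(attr(fs, "is_effect"), c(FALSE, TRUE, TRUE))
  expect_error(model_spec("count", "zi_gamma"), "frequency")
  expect_error(model_spec("count", "poisson", "mean_and_zi"), "frequency")
})

test_that("analyze_dataset finds a strong effect and not a null", {
  ds <- small_count_ds(seed = 61, strength = 1.5)
  r <- analyze_dataset(ds, n_iter = 2000, n_draws = 600, seed = 3)
  expect_true(r$found)
  expect_length(r$log_bml, 6)
  ds0 <- small_count_ds(seed = 62, effect_present = FALSE)
  r0 <- analyze_dataset(ds0, n_iter = 2000, n_draws = 600, seed = 4)
  expect_false(r0$found)
  fr <- to_frequency(ds)
  rf <- analyze_dataset(fr, n_iter = 2000, n_draws = 600, seed = 5)
  expect_length(rf$log_bml, 3)
})
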