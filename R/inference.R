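#' Analysis model specification
#'
#' Defines one candidate model for a dataset. Count models (Poisson, negative
#' binomial, zero-inflated negative binomial) always include `log(flowers)`
#' as an offset so parameters are per-flower rates; frequency models (the
#' zero-inflated gamma) never see the exposure. `effect_structure` selects the
#' no-effect model (`"none"`), an effect on the expectancy only
#' (`"mean_only"`), or — frequency models only — an effect on both the
#' expectancy and the zero-inflation probability (`"mean_and_zi"`).
#'
#' @param data_kind `"count"` or `"frequency"`.
#' @param family `"poisson"`, `"negbinom"`, `"zi_negbinom"` (count) or
#'   `"zi_gamma"` (frequency).
#' @param effect_structure `"none"`, `"mean_only"` or `"mean_and_zi"`.
#' @param effect_type effect type as in [effect_spec()] (ignored when
#'   `effect_structure = "none"`).
#' @param n_categories categories for random effect types.
#' @param p0_form orientation of the zero-inflation link, see
#'   [zero_inflation_prob()].
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(data_kind = c("count", "frequency"),
                       family = c("poisson", "negbinom", "zi_negbinom",
                                  "zi_gamma"),
                       effect_structure = c("none", "mean_only", "mean_and_zi"),
                       effect_type = "fixed_categorical", n_categories = 5L,
                       p0_form = c("decreasing", "literal")) {
  data_kind <- match.arg(data_kind)
  family <- match.arg(family)
  effect_structure <- match.arg(effect_structure)
  p0_form <- match.arg(p0_form)
  if (data_kind == "count" && family == "zi_gamma")
    stop("zi_gamma is a frequency model")
  if (data_kind == "frequency" && family != "zi_gamma")
    stop("frequency data are modelled with the zi_gamma family")
  if (effect_structure == "mean_and_zi" && data_kind != "frequency")
    stop("effect_structure 'mean_and_zi' is only defined for frequency models")
  effect_type <- match.arg(effect_type,
                           c("fixed_categorical", "fixed_linear",
                             "random_intercept", "random_slope"))
  structure(list(data_kind = data_kind, family = family,
                 effect_structure = effect_structure, effect_type = effect_type,
                 n_categories = as.integer(n_categories), p0_form = p0_form),
            class = "model_spec")
}

#' Default prior hyperparameters
#'
#' Wide but informative priors centred at the simulation study's operating
#' point, all overridable: `log(lambda0) ~ N(log 0.02, 2)`; fixed-effect
#' `beta ~ N(0, 2)`; random-effect scale `sigma ~ half-Normal(1)`;
#' negative-binomial `log(k) ~ N(log 10, 2)`; zero-inflation
#' `logit(p_zi) ~ N(-2, 2)`; gamma `log(shape) ~ N(0, 2)`; responsiveness
#' `g ~ N(0, 3)`; zero-inflation effect `beta_zi ~ N(0, 2)`.
#'
#' @param ... named overrides, each a `c(location, scale)` pair (for `sigma`
#'   a single half-normal scale).
#' @return named list of prior hyperparameters.
#' @export
default_priors <- function(...) {
  pr <- list(log_lambda0 = c(log(0.02), 2), beta = c(0, 2), sigma_scale = 1,
             log_k = c(log(10), 2), logit_pzi = c(-2, 2), log_shape = c(0, 2),
             g = c(0, 3), beta_zi = c(0, 2))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(pr)) stop("unknown prior component: ", nm)
    pr[[nm]] <- over[[nm]]
  }
  pr
}

# Parameter layout for a model: names, prior roles and the index bundle the
# C++ layer needs. Roles: 0 normal, 1 log(half-normal scale), 2 latent.
param_table <- function(model, priors = default_priors()) {
  stopifnot(inherits(model, "model_spec"))
  nm <- "log_lambda0"; role <- 0L
  pm <- priors$log_lambda0[1]; ps <- priors$log_lambda0[2]
  idx <- list(i_loglam = 0L, i_beta = -1L, i_logsigma = -1L, i_latent0 = -1L,
              n_latent = 0L, i_logk = -1L, i_logitpzi = -1L, i_logshape = -1L,
              i_g = -1L, i_betazi = -1L)
  add <- function(name, r, m, s) {
    nm <<- c(nm, name); role <<- c(role, r); pm <<- c(pm, m); ps <<- c(ps, s)
    length(nm) - 1L # 0-based index of the added coordinate
  }
  if (model$effect_structure != "none") {
    if (model$effect_type %in% c("fixed_categorical", "fixed_linear")) {
      idx$i_beta <- add("beta", 0L, priors$beta[1], priors$beta[2])
    } else {
      idx$i_logsigma <- add("log_sigma", 1L, 0, priors$sigma_scale)
      lat <- if (model$effect_type == "random_intercept") "eps" else "b"
      for (j in seq_len(model$n_categories)) {
        k <- add(paste0(lat, j), 2L, 0, NA)
        if (j == 1) idx$i_latent0 <- k
      }
      idx$n_latent <- model$n_categories
    }
  }
  if (model$family %in% c("negbinom", "zi_negbinom"))
    idx$i_logk <- add("log_k", 0L, priors$log_k[1], priors$log_k[2])
  if (model$family == "zi_negbinom")
    idx$i_logitpzi <- add("logit_pzi", 0L, priors$logit_pzi[1], priors$logit_pzi[2])
  if (model$family == "zi_gamma") {
    idx$i_logshape <- add("log_shape", 0L, priors$log_shape[1], priors$log_shape[2])
    idx$i_g <- add("g", 0L, priors$g[1], priors$g[2])
    if (model$effect_structure == "mean_and_zi")
      idx$i_betazi <- add("beta_zi", 0L, priors$beta_zi[1], priors$beta_zi[2])
  }
  list(names = nm, role = as.integer(role), prior_mean = pm, prior_sd = ps,
       idx = idx, d = length(nm))
}

model_ints <- function(model, pt) {
  kinds <- c(count = 0L, frequency = 1L)
  fams <- c(poisson = 0L, negbinom = 1L, zi_negbinom = 2L, zi_gamma = 3L)
  structs <- c(none = 0L, mean_only = 1L, mean_and_zi = 2L)
  types <- c(fixed_categorical = 0L, fixed_linear = 1L, random_intercept = 2L,
             random_slope = 3L)
  c(data_kind = kinds[[model$data_kind]], family = fams[[model$family]],
    effect_structure = structs[[model$effect_structure]],
    effect_type = types[[model$effect_type]],
    unlist(pt$idx),
    p0_literal = if (model$p0_form == "literal") 1L else 0L)
}

model_data <- function(model, dataset) {
  if (model$data_kind == "count") {
    if (!inherits(dataset, "count_dataset") && is.null(dataset$visits))
      stop("count model needs a dataset with a `visits` column")
    y <- as.numeric(dataset$visits)
    flowers <- as.numeric(dataset$flowers)
  } else {
    if (is.null(dataset$freq))
      stop("frequency model needs a dataset with a `freq` column")
    y <- as.numeric(dataset$freq)
    flowers <- rep(1, nrow(dataset))
  }
  x <- dataset$x
  x[is.na(x)] <- 0
  cat0 <- dataset$category
  cat0[is.na(cat0)] <- 1L
  list(y = y, flowers = flowers, x = as.numeric(x),
       cat = as.integer(cat0) - 1L)
}

#' Model log-likelihood at a parameter vector
#'
#' Sums the per-row log densities of `model` over `dataset` at the
#' unconstrained parameter vector `theta` (ordering as in the `param_names`
#' of [run_mcmc()]; see Details). Count models use mean
#' `flowers * exp(log_lambda0 + effect term)`; frequency models evaluate the
#' zero-inflated gamma at `mu = exp(log_lambda0 + effect term)`. For random
#' effect types the per-category latent effects are part of `theta`.
#'
#' This R implementation is independent of the compiled likelihood used by
#' the sampler and serves as its cross-check.
#'
#' @param model a [model_spec()].
#' @param dataset a count or frequency dataset.
#' @param theta numeric parameter vector on the unconstrained scale.
#' @param priors prior list (only used to determine the parameter layout).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, dataset, theta, priors = default_priors()) {
  pt <- param_table(model, priors)
  if (length(theta) != pt$d)
    stop("theta has length ", length(theta), ", expected ", pt$d)
  md <- model_data(model, dataset)
  i <- pt$idx
  eta <- rep(theta[i$i_loglam + 1], length(md$y))
  et <- rep(0, length(md$y))
  if (model$effect_structure != "none") {
    et <- switch(model$effect_type,
      fixed_categorical = , fixed_linear = theta[i$i_beta + 1] * md$x,
      random_intercept = theta[i$i_latent0 + 1 + md$cat],
      random_slope = theta[i$i_latent0 + 1 + md$cat] * md$x)
    eta <- eta + et
  }
  if (model$data_kind == "count") {
    m <- md$flowers * exp(eta)
    ll <- switch(model$family,
      poisson = stats::dpois(md$y, m, log = TRUE),
      negbinom = stats::dnbinom(md$y, size = exp(theta[i$i_logk + 1]), mu = m,
                                log = TRUE),
      zi_negbinom = {
        pzi <- stats::plogis(theta[i$i_logitpzi + 1])
        base <- stats::dnbinom(md$y, size = exp(theta[i$i_logk + 1]), mu = m,
                               log = TRUE)
        ifelse(md$y == 0,
               log(pzi + (1 - pzi) * exp(base)),
               log1p(-pzi) + base)
      })
  } else {
    h <- theta[i$i_g + 1] + eta
    lp0 <- if (model$p0_form == "literal") h else -h
    if (model$effect_structure == "mean_and_zi") {
      u <- if (model$effect_type %in% c("fixed_categorical", "fixed_linear"))
        md$x else et
      lp0 <- lp0 + theta[i$i_betazi + 1] * u
    }
    shape <- exp(theta[i$i_logshape + 1])
    mu <- exp(eta)
    ll <- ifelse(md$y == 0, stats::plogis(lp0, log.p = TRUE),
                 stats::plogis(-lp0, log.p = TRUE) +
                   stats::dgamma(md$y, shape = shape, scale = mu / shape,
                                 log = TRUE))
  }
  sum(ll)
}

#' Run the MCMC sampler for one model
#'
#' Adaptive random-walk Metropolis on the unconstrained (log/logit) parameter
#' scale: joint Gaussian proposals, global step size adapted towards a 0.234
#' acceptance rate during burn-in, per-coordinate scales tracked from the
#' chain history, adaptation frozen after burn-in. Chains start overdispersed
#' around the prior centre.
#'
#' @param model a [model_spec()].
#' @param dataset the dataset to fit.
#' @param priors prior list from [default_priors()].
#' @param n_iter iterations per chain (default 10000).
#' @param n_chains number of chains (default 2).
#' @param burn_frac fraction discarded as burn-in (default 0.5).
#' @param thin thinning interval (default 1).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @return an object of class `posterior_chains`: list with `draws` (one
#'   matrix per chain, post burn-in), `logpost`, `accept_rate`, `rhat`,
#'   `param_names`, `model`, `converged` (all Rhat < 1.1).
#' @export
run_mcmc <- function(model, dataset, priors = default_priors(),
                     n_iter = 10000L, n_chains = 2L, burn_frac = 0.5,
                     thin = 1L, seed = NULL) {
  pt <- param_table(model, priors)
  mi <- model_ints(model, pt)
  md <- model_data(model, dataset)
  n_burn <- as.integer(n_iter * burn_frac)
  start0 <- ifelse(pt$role == 1L, log(0.5), ifelse(pt$role == 2L, 0, pt$prior_mean))
  chains <- vector("list", n_chains)
  lps <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    jitter <- ifelse(pt$role == 2L, 0.1, 0.5)
    theta0 <- start0 + stats::rnorm(pt$d, 0, jitter)
    res <- .cp_mcmc_chain(mi, theta0, md$y, md$flowers, md$x, md$cat,
                          pt$role, pt$prior_mean,
                          ifelse(is.na(pt$prior_sd), 1, pt$prior_sd),
                          pt$idx$i_logsigma, as.integer(n_iter), n_burn,
                          as.integer(thin))
    colnames(res$draws) <- pt$names
    chains[[ch]] <- res$draws
    lps[[ch]] <- res$logpost
    acc[ch] <- res$accept_rate
  }
  rh <- rhat(chains)
  structure(list(draws = chains, logpost = lps, accept_rate = acc, rhat = rh,
                 param_names = pt$names, model = model, priors = priors,
                 n_iter = n_iter, n_burn = n_burn, seed = seed,
                 converged = all(is.finite(rh) & rh < 1.1)),
            class = "posterior_chains")
}

#' Potential scale reduction factor
#'
#' Gelman-Rubin Rhat per parameter across chains (no within-chain split;
#' chains are expected to be started overdispersed).
#'
#' @param chains list of draw matrices with identical dimensions.
#' @return named numeric vector of Rhat values.
#' @export
rhat <- function(chains) {
  m <- length(chains)
  if (m < 2) return(stats::setNames(rep(NA_real_, ncol(chains[[1]])),
                                    colnames(chains[[1]])))
  n <- nrow(chains[[1]])
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    x <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W <= .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0) -> r
  stats::setNames(r, colnames(chains[[1]]))
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("<posterior_chains> ", x$model$family, "/", x$model$effect_structure,
      ", ", length(x$draws), " chains x ", nrow(x$draws[[1]]), " kept draws\n",
      "  accept rates: ", paste(round(x$accept_rate, 3), collapse = ", "),
      "\n  max Rhat: ", round(max(x$rhat), 4),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

# multivariate t draws and log density (moment-matched importance density)
rmvt_is <- function(n, mean, sigma, df) {
  d <- length(mean)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), n, d) %*% L
  u <- stats::rchisq(n, df) / df
  sweep(z / sqrt(u), 2, mean, "+")
}

dmvt_is <- function(x, mean, sigma, df) {
  d <- length(mean)
  L <- chol(sigma)
  xc <- sweep(x, 2, mean)
  q <- colSums(backsolve(L, t(xc), transpose = TRUE)^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - d / 2 * log(df * pi) -
    sum(log(diag(L))) - (df + d) / 2 * log1p(q / df)
}

#' Estimate the Bayesian model likelihood by importance sampling
#'
#' Fits a heavy-tailed elliptical importance density — a multivariate t,
#' moment-matched to the pooled posterior draws, `df` degrees of freedom — on
#' the unconstrained scale, and estimates
#' `log P(D | M) = log mean( prior x likelihood / importance density )`
#' over `n_draws` independent draws. The Monte Carlo standard error of the
#' log estimate comes from the delta method; an effective sample size below
#' `ess_threshold` raises a warning and sets the `degenerate` flag.
#'
#' For random-effect models the per-category latent effects are coordinates
#' of the posterior, so the importance-sampling integral marginalises them
#' together with the hyperparameters.
#'
#' @param chains a `posterior_chains` object from [run_mcmc()], or `NULL` if
#'   `draws` is supplied directly.
#' @param model,dataset,priors the fitted model; ignored when `log_target`
#'   is supplied.
#' @param n_draws number of importance draws (default 2000).
#' @param df degrees of freedom of the t importance density (default 5).
#' @param seed optional RNG seed.
#' @param draws optional matrix of posterior draws (rows = draws), used
#'   instead of `chains`.
#' @param log_target optional function(matrix) returning log(prior x
#'   likelihood) per row; replaces the model/dataset pair. This is the hook
#'   the conjugate-oracle tests use.
#' @param ess_threshold degeneracy threshold on the importance ESS.
#' @return object of class `bml_estimate`: `log_bml`, `mc_se`, `n_draws`,
#'   `ess`, `degenerate`.
#' @export
estimate_log_bml <- function(chains = NULL, model = NULL, dataset = NULL,
                             priors = default_priors(), n_draws = 2000L,
                             df = 5, seed = NULL, draws = NULL,
                             log_target = NULL, ess_threshold = 50) {
  if (is.null(draws)) {
    stopifnot(inherits(chains, "posterior_chains"))
    draws <- do.call(rbind, chains$draws)
    if (is.null(model)) model <- chains$model
  }
  if (is.null(log_target)) {
    pt <- param_table(model, priors)
    mi <- model_ints(model, pt)
    md <- model_data(model, dataset)
    log_target <- function(th) {
      tt <- .cp_target_terms(mi, th, md$y, md$flowers, md$x, md$cat, pt$role,
                             pt$prior_mean,
                             ifelse(is.na(pt$prior_sd), 1, pt$prior_sd),
                             pt$idx$i_logsigma)
      tt[, 1] + tt[, 2]
    }
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(draws)
  S <- stats::cov(draws)
  diag(S) <- diag(S) + 1e-8
  th <- rmvt_is(n_draws, mu, S, df)
  l <- log_target(th) - dmvt_is(th, mu, S, df)
  keep <- is.finite(l) | l == -Inf
  l[!keep] <- -Inf
  mx <- max(l)
  w <- exp(l - mx)
  log_bml <- mx + log(mean(w))
  mc_se <- stats::sd(w) / (mean(w) * sqrt(n_draws))
  ess <- sum(w)^2 / sum(w^2)
  degenerate <- ess < ess_threshold
  if (degenerate)
    warning("importance weights are degenerate (ESS = ", round(ess, 1), ")")
  structure(list(log_bml = log_bml, mc_se = mc_se,
                 n_draws = as.integer(n_draws), ess = ess,
                 degenerate = degenerate),
            class = "bml_estimate")
}

#' @export
print.bml_estimate <- function(x, ...) {
  cat("<bml_estimate> log BML = ", format(x$log_bml), " (mc se ",
      format(x$mc_se, digits = 3), ", ESS ", round(x$ess), ")",
      if (x$degenerate) "  [DEGENERATE]", "\n", sep = "")
  invisible(x)
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' `P(M_i | D) = P(D | M_i) P(M_i) / sum_j P(D | M_j) P(M_j)`, computed
#' stably in log space.
#'
#' @param log_bmls numeric vector of log marginal likelihoods.
#' @param prior_probs prior model probabilities (default equal); must sum
#'   to 1.
#' @return probability vector summing to 1.
#' @export
posterior_model_probs <- function(log_bmls,
                                  prior_probs = rep(1 / length(log_bmls),
                                                    length(log_bmls))) {
  if (length(log_bmls) == 0) stop("empty model set")
  if (abs(sum(prior_probs) - 1) > 1e-8) stop("prior_probs must sum to 1")
  lp <- log_bmls + ifelse(prior_probs > 0, log(prior_probs), -Inf)
  p <- exp(lp - logsumexp(lp))
  p / sum(p)
}

#' Declare whether an effect was found
#'
#' The decision rule of the model-selection study: compare the best effect
#' model against the best no-effect model by Bayes factor. The score is the
#' difference of the two best log marginal likelihoods; an effect is declared
#' when `score > log(threshold)` (strictly), so `threshold = 1` is the
#' equal-prior highest-BML rule and larger thresholds demand more evidence.
#'
#' @param log_bmls numeric vector of log BMLs.
#' @param is_effect logical vector flagging which entries are effect models.
#' @param threshold positive Bayes-factor threshold (default 1).
#' @return list with `found` (logical) and `score` (log Bayes factor between
#'   the best effect and best no-effect model).
#' @export
detect_effect <- function(log_bmls, is_effect, threshold = 1) {
  stopifnot(length(log_bmls) == length(is_effect), threshold > 0)
  if (!any(is_effect) || all(is_effect))
    stop("need at least one effect and one no-effect model")
  score <- max(log_bmls[is_effect]) - max(log_bmls[!is_effect])
  list(found = isTRUE(score > log(threshold)), score = score)
}

#' The candidate model sets of the study
#'
#' `count_model_set()`: six count models — Poisson, negative binomial and
#' zero-inflated negative binomial, each with and without an effect.
#' `frequency_model_set()`: three frequency models — zero-inflated gamma with
#' no effect, with an effect on the expectancy only, and with an effect on
#' both expectancy and zero-inflation.
#'
#' @param effect_type the (known) effect type the effect models use.
#' @param n_categories categories for random effect types.
#' @param p0_form zero-inflation link orientation (frequency set).
#' @return named list of [model_spec()]s with attribute `is_effect`.
#' @export
count_model_set <- function(effect_type, n_categories = 5L) {
  fams <- c("poisson", "negbinom", "zi_negbinom")
  out <- list()
  for (f in fams) {
    out[[paste0(f, "_null")]] <-
      model_spec("count", f, "none", effect_type, n_categories)
    out[[paste0(f, "_effect")]] <-
      model_spec("count", f, "mean_only", effect_type, n_categories)
  }
  structure(out, is_effect = grepl("_effect$", names(out)))
}

#' @rdname count_model_set
#' @export
frequency_model_set <- function(effect_type, n_categories = 5L,
                                p0_form = "decreasing") {
  out <- list(
    zi_gamma_null = model_spec("frequency", "zi_gamma", "none", effect_type,
                               n_categories, p0_form),
    zi_gamma_mean = model_spec("frequency", "zi_gamma", "mean_only",
                               effect_type, n_categories, p0_form),
    zi_gamma_mean_zi = model_spec("frequency", "zi_gamma", "mean_and_zi",
                                  effect_type, n_categories, p0_form))
  structure(out, is_effect = c(FALSE, TRUE, TRUE))
}

#' Fit every candidate model to one dataset and score the effect
#'
#' Runs [run_mcmc()] and [estimate_log_bml()] for each model in the set
#' matching the dataset kind, then applies [detect_effect()].
#'
#' @param dataset a `count_dataset` or `frequency_dataset`.
#' @param effect_type effect type the effect models should assume (defaults
#'   to the one recorded in the dataset metadata).
#' @param priors prior list.
#' @param n_iter,n_chains,n_draws MCMC / importance-sampling sizes.
#' @param threshold Bayes-factor declaration threshold.
#' @param seed integer seed; model `i` uses `seed + 1000 * i`.
#' @param p0_form zero-inflation link orientation for frequency models.
#' @return list with `log_bml`, `mc_se` (named vectors), `score`, `found`,
#'   `converged` (per model), `degenerate` (per model).
#' @export
analyze_dataset <- function(dataset, effect_type = NULL,
                            priors = default_priors(), n_iter = 4000L,
                            n_chains = 2L, n_draws = 1000L, threshold = 1,
                            seed = NULL, p0_form = "decreasing") {
  if (is.null(effect_type)) {
    es <- attr(dataset, "effect_spec")
    if (is.null(es)) stop("`effect_type` not given and not in metadata")
    effect_type <- es$effect_type
    ncat <- es$n_categories
  } else ncat <- 5L
  models <- if (inherits(dataset, "frequency_dataset") ||
                (!inherits(dataset, "count_dataset") && !is.null(dataset$freq)))
    frequency_model_set(effect_type, ncat, p0_form)
  else count_model_set(effect_type, ncat)
  is_eff <- attr(models, "is_effect")
  lb <- se <- numeric(length(models))
  conv <- deg <- logical(length(models))
  for (i in seq_along(models)) {
    si <- if (is.null(seed)) NULL else seed + 1000L * i
    ch <- run_mcmc(models[[i]], dataset, priors, n_iter = n_iter,
                   n_chains = n_chains, seed = si)
    bml <- withCallingHandlers(
      estimate_log_bml(ch, models[[i]], dataset, priors, n_draws = n_draws,
                       seed = si),
      warning = function(w) invokeRestart("muffleWarning"))
    lb[i] <- bml$log_bml
    se[i] <- bml$mc_se
    conv[i] <- ch$converged
    deg[i] <- bml$degenerate
  }
  names(lb) <- names(se) <- names(conv) <- names(deg) <- names(models)
  det <- detect_effect(lb, is_eff, threshold)
  list(log_bml = lb, mc_se = se, score = det$score, found = det$found,
       converged = conv, degenerate = deg)
}
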