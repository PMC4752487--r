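#' Effect specification for simulated visitation data
#'
#' Describes the hypothetical external process driving variation in the
#' expected visitation rate \eqn{\lambda} (visits per flower per observation
#' period), always through a log link:
#'
#' * `fixed_categorical`: binary covariate, \eqn{\log\lambda = \log\lambda_0 + \beta x}.
#' * `fixed_linear`: continuous covariate on \[0, 1\], same formula.
#' * `random_intercept`: \eqn{\log\lambda = \log\lambda_0 + \epsilon_x},
#'   \eqn{\epsilon_x \sim N(0, \sigma_{RE}^2)} drawn once per category per dataset.
#' * `random_slope`: \eqn{\log\lambda = \log\lambda_0 + \beta_x y},
#'   \eqn{\beta_x \sim N(0, \sigma_{RS}^2)} per category, `y` continuous.
#'
#' `strength` is \eqn{\beta} for the fixed effects and the random-effect
#' standard deviation \eqn{\sigma} otherwise. With `effect_present = FALSE`
#' the rate is \eqn{\lambda_0} everywhere regardless of `strength`.
#'
#' @param effect_type one of `"fixed_categorical"`, `"fixed_linear"`,
#'   `"random_intercept"`, `"random_slope"`.
#' @param lambda0 baseline expected visits per flower (default 0.02).
#' @param strength effect magnitude (see above).
#' @param n_categories number of categories for random effects (default 5).
#' @param effect_present logical.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(effect_type = c("fixed_categorical", "fixed_linear",
                                        "random_intercept", "random_slope"),
                        lambda0 = 0.02, strength = 0, n_categories = 5L,
                        effect_present = TRUE) {
  effect_type <- match.arg(effect_type)
  stopifnot(is.finite(lambda0), lambda0 > 0, is.finite(strength),
            n_categories >= 1)
  if (effect_type %in% c("random_intercept", "random_slope") && strength < 0)
    stop("random-effect `strength` is a standard deviation and must be >= 0")
  if (!effect_present) strength <- 0
  structure(list(effect_type = effect_type, lambda0 = lambda0,
                 strength = strength, n_categories = as.integer(n_categories),
                 effect_present = isTRUE(effect_present)),
            class = "effect_spec")
}

#' Default dataset size for an effect type
#'
#' 30 rows for fixed effects, 75 (15 per category) for a random intercept and
#' 300 (60 per category) for a random slope: random effects need enough rows
#' per category for their distribution to be detectable.
#' @param effect_type effect type string.
#' @return integer number of rows.
#' @export
default_n_rows <- function(effect_type) {
  switch(effect_type,
         fixed_categorical = 30L, fixed_linear = 30L,
         random_intercept = 75L, random_slope = 300L,
         stop("unknown effect type: ", effect_type))
}

#' Solve the exposure distribution for a coverage constraint
#'
#' The number of flowers observed per event is drawn from a negative binomial
#' adjusted so that a `coverage` probability mass falls on `[lower, upper]`,
#' split as two equal tails: `P(N < lower) = P(N > upper) = (1 - coverage)/2`.
#' The two tail equations determine the two NB parameters `(nb_mean, nb_size)`
#' numerically.
#'
#' @param lower,upper integer bounds (defaults 10 and 1000).
#' @param coverage probability mass on the interval (default 0.95).
#' @return an object of class `exposure_spec` with fields `nb_mean`,
#'   `nb_size`, `lower`, `upper`, `coverage`.
#' @examples
#' ex <- solve_exposure_params()
#' pnbinom(999, size = ex$nb_size, mu = ex$nb_mean) -
#'   pnbinom(9, size = ex$nb_size, mu = ex$nb_mean) # ~0.95
#' @export
solve_exposure_params <- function(lower = 10L, upper = 1000L, coverage = 0.95) {
  stopifnot(lower >= 1, lower < upper, coverage > 0, coverage < 1)
  tail <- (1 - coverage) / 2
  obj <- function(p) {
    mu <- exp(p[1]); size <- exp(p[2])
    lo <- stats::pnbinom(lower - 1, size = size, mu = mu)
    hi <- stats::pnbinom(upper, size = size, mu = mu, lower.tail = FALSE)
    (lo - tail)^2 + (hi - tail)^2
  }
  # geometric midpoint of the interval is a serviceable start for the mean
  start <- c(log(sqrt(lower * upper)), 0)
  opt <- stats::optim(start, obj, control = list(reltol = 1e-14, maxit = 10000))
  if (opt$convergence != 0 || opt$value > 1e-8)
    stop("exposure solver did not converge: value = ", format(opt$value),
         ", convergence code = ", opt$convergence)
  spec <- structure(list(nb_mean = exp(opt$par[1]), nb_size = exp(opt$par[2]),
                         lower = as.integer(lower), upper = as.integer(upper),
                         coverage = coverage),
                    class = "exposure_spec")
  got <- stats::pnbinom(upper, size = spec$nb_size, mu = spec$nb_mean) -
    stats::pnbinom(lower - 1, size = spec$nb_size, mu = spec$nb_mean)
  if (abs(got - coverage) > 1e-3)
    stop("exposure solution violates the coverage invariant: ", format(got))
  spec
}

#' Sample exposures (numbers of flowers)
#'
#' Negative-binomial draws under an [solve_exposure_params()] spec; draws of
#' zero flowers are redrawn, so every returned value is >= 1.
#'
#' @param n number of draws.
#' @param spec an `exposure_spec`.
#' @return integer vector of flower counts, all >= 1.
#' @export
sample_exposure <- function(n, spec) {
  stopifnot(inherits(spec, "exposure_spec"))
  out <- stats::rnbinom(n, size = spec$nb_size, mu = spec$nb_mean)
  while (any(z <- out == 0))
    out[z] <- stats::rnbinom(sum(z), size = spec$nb_size, mu = spec$nb_mean)
  out
}

#' Build covariates for a dataset
#'
#' * `fixed_categorical`: Bernoulli x with P(x = 1) = 0.6 ("yes") and
#'   P(x = 0) = 0.4 ("no").
#' * `fixed_linear`: x ~ Uniform(0, 1).
#' * `random_intercept`: categories 1..`n_categories` traversed systematically
#'   in a fixed cycle, equal counts per category.
#' * `random_slope`: the category cycle crossed with an equally spaced grid of
#'   x values on \[0, 1\] within each category.
#'
#' @param effect_type effect type string.
#' @param n number of rows; must be divisible by `n_categories` for random
#'   effects.
#' @param n_categories number of categories (random effects).
#' @return data.frame with columns `category` (integer or NA) and `x`
#'   (numeric or NA).
#' @export
make_covariates <- function(effect_type, n, n_categories = 5L) {
  n <- as.integer(n)
  switch(effect_type,
    fixed_categorical = data.frame(category = NA_integer_,
                                   x = as.numeric(stats::runif(n) < 0.6)),
    fixed_linear = data.frame(category = NA_integer_, x = stats::runif(n)),
    random_intercept = {
      if (n %% n_categories != 0)
        stop("`n` must be divisible by `n_categories` for random effects")
      data.frame(category = rep_len(seq_len(n_categories), n), x = NA_real_)
    },
    random_slope = {
      if (n %% n_categories != 0)
        stop("`n` must be divisible by `n_categories` for random effects")
      per <- n %/% n_categories
      data.frame(category = rep(seq_len(n_categories), each = per),
                 x = rep(seq(0, 1, length.out = per), times = n_categories))
    },
    stop("unknown effect type: ", effect_type))
}

#' Draw the per-category random effects for one dataset
#'
#' @param spec an [effect_spec()]; returns `NULL` for fixed effects.
#' @return numeric vector of length `n_categories` (the \eqn{\epsilon_x} or
#'   \eqn{\beta_x} draws), or `NULL`.
#' @export
draw_random_effects <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  if (!spec$effect_type %in% c("random_intercept", "random_slope")) return(NULL)
  stats::rnorm(spec$n_categories, 0, spec$strength)
}

#' Expected visitation rate for covariate rows
#'
#' Applies the log-link effect formula of an [effect_spec()] to covariate rows
#' (as produced by [make_covariates()]), returning \eqn{\lambda} per row.
#'
#' @param spec an [effect_spec()].
#' @param covariates data.frame with `category` and `x` columns.
#' @param random_draws per-category draws from [draw_random_effects()];
#'   required iff the effect type is random and the effect is present.
#' @return positive numeric vector of per-flower rates.
#' @export
effect_rate <- function(spec, covariates, random_draws = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  n <- nrow(covariates)
  if (!spec$effect_present) return(rep(spec$lambda0, n))
  lp <- switch(spec$effect_type,
    fixed_categorical = ,
    fixed_linear = spec$strength * covariates$x,
    random_intercept = {
      if (is.null(random_draws)) stop("missing per-category random draws")
      random_draws[covariates$category]
    },
    random_slope = {
      if (is.null(random_draws)) stop("missing per-category random draws")
      random_draws[covariates$category] * covariates$x
    })
  spec$lambda0 * exp(lp)
}

#' Simulate one count dataset
#'
#' Builds each observation event independently in three steps: sample the
#' exposure (number of flowers), choose the covariate value, then sample the
#' visit count from the generating family with mean
#' `flowers * lambda(covariates)`. For random effects the per-category draws
#' are made once per dataset.
#'
#' @param family generating [count_family()].
#' @param spec an [effect_spec()].
#' @param exposure an exposure spec from [solve_exposure_params()].
#' @param n rows (default [default_n_rows()] for the effect type).
#' @param seed optional integer; if given, seeds R's RNG for reproducibility
#'   and is recorded in the metadata.
#' @return a `count_dataset`: data.frame with columns
#'   `flowers`, `category`, `x`, `visits` and attributes `effect_spec`,
#'   `family`, `exposure_spec`, `random_draws`, `seed`.
#' @export
simulate_dataset <- function(family, spec, exposure,
                             n = default_n_rows(spec$effect_type),
                             seed = NULL) {
  stopifnot(inherits(family, "count_family"), inherits(spec, "effect_spec"),
            inherits(exposure, "exposure_spec"))
  if (!is.null(seed)) set.seed(seed)
  flowers <- sample_exposure(n, exposure)
  cov <- make_covariates(spec$effect_type, n, spec$n_categories)
  rd <- if (spec$effect_present) draw_random_effects(spec) else NULL
  lambda <- effect_rate(spec, cov, rd)
  visits <- count_sample(n, lambda, flowers, family)
  ds <- data.frame(flowers = flowers, category = cov$category, x = cov$x,
                   visits = as.integer(visits))
  structure(ds, effect_spec = spec, family = family, exposure_spec = exposure,
            random_draws = rd, seed = seed,
            class = c("count_dataset", "data.frame"))
}

#' Derive the frequency representation of a count dataset
#'
#' Divides visits by flowers and drops the exposure column — deliberately
#' discarding information, exactly as when visitation frequencies are
#' reported instead of raw counts (100 visits in 200 flowers and 2 visits in
#' 4 flowers both become 0.5).
#'
#' @param ds a `count_dataset` from [simulate_dataset()].
#' @return a `frequency_dataset` with columns `category`, `x`, `freq` and the
#'   same metadata attributes.
#' @export
to_frequency <- function(ds) {
  stopifnot(inherits(ds, "count_dataset"))
  if (any(ds$flowers <= 0)) stop("zero flowers: cannot form a frequency")
  out <- data.frame(category = ds$category, x = ds$x,
                    freq = ds$visits / ds$flowers)
  structure(out, effect_spec = attr(ds, "effect_spec"),
            family = attr(ds, "family"),
            exposure_spec = attr(ds, "exposure_spec"),
            random_draws = attr(ds, "random_draws"), seed = attr(ds, "seed"),
            class = c("frequency_dataset", "data.frame"))
}

#' Write / read a dataset as CSV with a JSON metadata sidecar
#'
#' Count datasets use columns `flowers,category,x,visits`; frequency datasets
#' `category,x,freq`. Metadata (effect spec, family, exposure spec, seed) goes
#' to `<path>.json`.
#'
#' @param ds a `count_dataset` or `frequency_dataset`.
#' @param path CSV file path.
#' @return `write_dataset`: the path, invisibly. `read_dataset`: the dataset
#'   with metadata restored.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "data.frame"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  spec <- attr(ds, "effect_spec")
  fam <- attr(ds, "family")
  expo <- attr(ds, "exposure_spec")
  meta <- list(kind = if (inherits(ds, "count_dataset")) "count" else "frequency",
               effect_spec = unclass(spec), family = unclass(fam),
               exposure_spec = unclass(expo),
               random_draws = attr(ds, "random_draws"), seed = attr(ds, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  # all-NA columns come back logical; restore the declared column types
  if (!is.null(df$category)) df$category <- as.integer(df$category)
  if (!is.null(df$x)) df$x <- as.numeric(df$x)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fam <- if (!is.null(meta$family))
    do.call(count_family, meta$family[!vapply(meta$family, is.null, TRUE)])
  spec <- if (!is.null(meta$effect_spec)) {
    s <- meta$effect_spec
    effect_spec(s$effect_type, s$lambda0, s$strength, s$n_categories,
                s$effect_present)
  }
  expo <- if (!is.null(meta$exposure_spec))
    structure(meta$exposure_spec, class = "exposure_spec")
  cls <- if (identical(meta$kind, "count")) "count_dataset" else "frequency_dataset"
  structure(df, effect_spec = spec, family = fam, exposure_spec = expo,
            random_draws = meta$random_draws, seed = meta$seed,
            class = c(cls, "data.frame"))
}
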