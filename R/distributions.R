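#' Count-distribution family descriptor
#'
#' Bundles a generating (or analysis) count distribution with exactly the
#' parameters that family needs. Supported families:
#'
#' * `"poisson"` — no extra parameters.
#' * `"negbinom"` — overdispersion `k`, variance \eqn{m + m^2/k} at mean `m`.
#' * `"lognormal_poisson"` — Poisson with a lognormal rate multiplier whose
#'   log-scale standard deviation is `sd`. With `lognormal_mean_one = TRUE`
#'   (default) the multiplier has expectation 1 (latent
#'   \eqn{\epsilon \sim N(-sd^2/2, sd^2)}), so the marginal mean is preserved;
#'   otherwise the multiplier has median 1.
#' * `"zi_negbinom"` — negative binomial with an extra point mass `p_zi` at 0.
#'
#' @param family one of `"poisson"`, `"negbinom"`, `"lognormal_poisson"`,
#'   `"zi_negbinom"`.
#' @param k positive overdispersion parameter (negative-binomial families).
#' @param sd nonnegative log-scale standard deviation (lognormal-Poisson).
#' @param p_zi zero-inflation probability in `[0, 1)` (`zi_negbinom` only).
#' @param lognormal_mean_one logical; see above.
#' @return an object of class `count_family`.
#' @examples
#' count_family("negbinom", k = 10)
#' count_family("lognormal_poisson", sd = 0.36)
#' @export
count_family <- function(family = c("poisson", "negbinom", "lognormal_poisson",
                                    "zi_negbinom"),
                         k = NULL, sd = NULL, p_zi = NULL,
                         lognormal_mean_one = TRUE) {
  family <- match.arg(family)
  if (family %in% c("negbinom", "zi_negbinom")) {
    if (is.null(k) || !is.finite(k) || k <= 0)
      stop("`k` must be a positive real for family '", family, "'")
  } else if (!is.null(k)) {
    stop("`k` is only meaningful for negative-binomial families")
  }
  if (family == "lognormal_poisson") {
    if (is.null(sd) || !is.finite(sd) || sd < 0)
      stop("`sd` must be a nonnegative real for lognormal_poisson")
  } else if (!is.null(sd)) {
    stop("`sd` is only meaningful for lognormal_poisson")
  }
  if (family == "zi_negbinom") {
    if (is.null(p_zi) || !is.finite(p_zi) || p_zi < 0 || p_zi >= 1)
      stop("`p_zi` must lie in [0, 1) for zi_negbinom")
  } else if (!is.null(p_zi)) {
    stop("`p_zi` is only meaningful for zi_negbinom")
  }
  structure(list(family = family, k = k, sd = sd, p_zi = p_zi,
                 lognormal_mean_one = isTRUE(lognormal_mean_one)),
            class = "count_family")
}

#' @export
print.count_family <- function(x, ...) {
  pars <- c(k = x$k, sd = x$sd, p_zi = x$p_zi)
  cat("<count_family> ", x$family,
      if (length(pars)) paste0(" (", paste(names(pars), "=", pars, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal Jacobi
# matrix); exact for polynomials up to degree 2n-1 against exp(-z^2).
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log probability mass of a visit count
#'
#' Evaluates the log pmf of the number of visits `y` observed on `flowers`
#' flowers when the per-flower visitation rate is `rate`, under the given
#' family. The mean is `m = flowers * rate` for every family. The
#' lognormal-Poisson pmf has no closed form and is evaluated by Gauss-Hermite
#' quadrature over the latent lognormal multiplier.
#'
#' @param y nonnegative integer count (vectorised).
#' @param rate positive per-flower visitation rate.
#' @param flowers positive number of flowers observed (the exposure).
#' @param family a [count_family()].
#' @param gh_nodes number of Gauss-Hermite nodes for lognormal-Poisson.
#' @return log probability, same length as `y`.
#' @examples
#' count_logpmf(0, rate = 0.02, flowers = 100, count_family("poisson")) # -2
#' @export
count_logpmf <- function(y, rate, flowers, family, gh_nodes = 40) {
  stopifnot(inherits(family, "count_family"))
  if (any(y < 0) || any(y != floor(y)))
    stop("`y` must contain nonnegative integers")
  if (any(rate <= 0) || any(flowers <= 0))
    stop("`rate` and `flowers` must be positive")
  m <- flowers * rate
  switch(family$family,
    poisson = stats::dpois(y, m, log = TRUE),
    negbinom = stats::dnbinom(y, size = family$k, mu = m, log = TRUE),
    zi_negbinom = {
      base <- stats::dnbinom(y, size = family$k, mu = m, log = TRUE)
      p <- family$p_zi
      out <- log1p(-p) + base
      z <- y == 0
      if (any(z))
        out[z] <- vapply(which(z), function(i)
          logsumexp(c(log(p), log1p(-p) + base[i])), 0)
      out
    },
    lognormal_poisson = {
      s <- family$sd
      if (s == 0) return(stats::dpois(y, m, log = TRUE))
      gh <- gauss_hermite(gh_nodes)
      mu_eps <- if (family$lognormal_mean_one) -s^2 / 2 else 0
      eps <- mu_eps + sqrt(2) * s * gh$nodes
      lw <- log(gh$weights) - 0.5 * log(pi)
      mm <- if (length(m) == 1) rep(m, length(y)) else m
      vapply(seq_along(y), function(i)
        logsumexp(lw + stats::dpois(y[i], mm[i] * exp(eps), log = TRUE)), 0)
    })
}

#' Sample visit counts
#'
#' Draws visit counts under a [count_family()] at per-flower `rate` over
#' `flowers` flowers. Uses R's global RNG stream (seed with [set.seed()]).
#' For the lognormal-Poisson family a latent multiplier is drawn per
#' observation so the marginal mean stays `flowers * rate` (mean-one
#' convention; see [count_family()]).
#'
#' @param n number of draws.
#' @param rate positive per-flower rate (scalar or length `n`).
#' @param flowers positive exposure (scalar or length `n`).
#' @param family a [count_family()].
#' @return integer vector of counts.
#' @export
count_sample <- function(n, rate, flowers, family) {
  stopifnot(inherits(family, "count_family"))
  if (any(rate <= 0) || any(flowers <= 0))
    stop("`rate` and `flowers` must be positive")
  m <- rep_len(flowers * rate, n)
  switch(family$family,
    poisson = stats::rpois(n, m),
    negbinom = stats::rnbinom(n, size = family$k, mu = m),
    zi_negbinom = {
      y <- stats::rnbinom(n, size = family$k, mu = m)
      y[stats::runif(n) < family$p_zi] <- 0L
      y
    },
    lognormal_poisson = {
      s <- family$sd
      mu_eps <- if (family$lognormal_mean_one) -s^2 / 2 else 0
      eps <- stats::rnorm(n, mu_eps, s)
      stats::rpois(n, m * exp(eps))
    })
}

#' Zero-inflation probability of the frequency model
#'
#' The zero-inflated gamma model for visitation frequencies links the
#' point mass at zero to the gamma expectancy `mu` through the
#' responsiveness parameter `g`. The default form
#' \deqn{p_0 = 1 / (1 + e^g \mu)}
#' decreases in `mu`: the smaller the expected number of visits, the more
#' likely an exact zero, which is the behaviour a zero-inflated visitation
#' model is meant to capture. The alternative `form = "literal"` uses
#' \eqn{p_0 = e^g \mu / (1 + e^g \mu)}, which increases in `mu`; both are
#' available because the two published statements of the link disagree in
#' orientation (see the methods vignette).
#'
#' @param mu positive gamma-component expectancy (visits per flower).
#' @param g real responsiveness parameter.
#' @param form `"decreasing"` (default) or `"literal"`.
#' @return probability in (0, 1), vectorised over `mu` and `g`.
#' @examples
#' zero_inflation_prob(1, 0) # 0.5
#' @export
zero_inflation_prob <- function(mu, g, form = c("decreasing", "literal")) {
  form <- match.arg(form)
  if (any(mu <= 0)) stop("`mu` must be positive")
  h <- g + log(mu)
  if (form == "decreasing") stats::plogis(-h) else stats::plogis(h)
}

#' Zero-inflated gamma parameter set
#'
#' @param mu positive expectancy of the gamma component.
#' @param shape positive gamma shape.
#' @param g zero-inflation responsiveness (see [zero_inflation_prob()]).
#' @param form orientation of the p0 link.
#' @return an object of class `zi_gamma_params`.
#' @export
zi_gamma_params <- function(mu, shape, g, form = c("decreasing", "literal")) {
  form <- match.arg(form)
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be positive")
  if (!is.finite(shape) || shape <= 0) stop("`shape` must be positive")
  if (!is.finite(g)) stop("`g` must be finite")
  structure(list(mu = mu, shape = shape, g = g, form = form),
            class = "zi_gamma_params")
}

#' Log density of the zero-inflated gamma frequency model
#'
#' A mixed distribution: point mass \eqn{p_0} at exactly zero (see
#' [zero_inflation_prob()]) and, with probability \eqn{1 - p_0}, a gamma
#' density with mean `mu` and shape `shape`.
#'
#' @param freq nonnegative observed frequency (visits per flower), vectorised.
#' @param params a [zi_gamma_params()].
#' @return log density (log probability for `freq = 0`).
#' @export
zi_gamma_logdensity <- function(freq, params) {
  stopifnot(inherits(params, "zi_gamma_params"))
  if (any(freq < 0)) stop("`freq` must be nonnegative")
  p0 <- zero_inflation_prob(params$mu, params$g, params$form)
  out <- numeric(length(freq))
  z <- freq == 0
  out[z] <- log(p0)
  out[!z] <- log1p(-p0) +
    stats::dgamma(freq[!z], shape = params$shape,
                  scale = params$mu / params$shape, log = TRUE)
  out
}

#' Sample from the zero-inflated gamma frequency model
#'
#' @param n number of draws.
#' @param params a [zi_gamma_params()].
#' @return nonnegative numeric vector with exact zeros.
#' @export
zi_gamma_sample <- function(n, params) {
  stopifnot(inherits(params, "zi_gamma_params"))
  p0 <- zero_inflation_prob(params$mu, params$g, params$form)
  y <- stats::rgamma(n, shape = params$shape, scale = params$mu / params$shape)
  y[stats::runif(n) < p0] <- 0
  y
}
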