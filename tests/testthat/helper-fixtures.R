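# Shared fixtures: everything is generated in code at test time.

# one exposure solve for the whole suite (deterministic)
exposure_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- solve_exposure_params()
    cache
  }
})

# a small fixed-categorical Poisson count dataset
small_count_ds <- function(seed = 42, n = 30, strength = 0.8,
                           effect_present = TRUE,
                           family = count_family("poisson")) {
  es <- effect_spec("fixed_categorical", strength = strength,
                    effect_present = effect_present)
  simulate_dataset(family, es, exposure_fixture(), n, seed = seed)
}

# closed-form log marginal likelihood of the Poisson-gamma conjugate model:
# y_i ~ Poisson(lambda f_i), lambda ~ Gamma(a, rate b)
poisson_gamma_log_marginal <- function(y, f, a, b) {
  S <- sum(y)
  sum(y * log(f) - lgamma(y + 1)) + a * log(b) - lgamma(a) +
    lgamma(a + S) - (a + S) * log(b + sum(f))
}
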