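---
title: "Counts versus derived frequencies: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counts versus derived frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pollination studies typically report flower visitation as a *frequency* —
visits per flower per unit time — even though the raw measurement is a count
of visits over a known exposure (the number of flowers watched for a fixed
period). Collapsing 100 visits in 200 flowers and 2 visits in 4 flowers into
the same number 0.5 throws away the exposure, and with it a great deal of
information when exposure varies between observation events. `countpower`
quantifies that loss. It simulates visitation datasets whose generating
process is fully known, analyses each dataset twice — once as counts with
`log(flowers)` as an offset, once as derived frequencies — and compares the
two analyses by their type-I/type-II error rates, ROC curves and the sample
size each needs to reach a target power.

## The generating process

Each observation event (row) is built independently in three steps.

**Exposure.** The number of flowers `N` is drawn from a negative binomial
whose two parameters are solved numerically so that
`P(N < 10) = P(N > 1000) = 0.025`, i.e. 95% of the mass lies on `[10, 1000]`
with symmetric tails (`solve_exposure_params()`; the solution is
`nb_mean ≈ 284.1`, `nb_size ≈ 1.118`). Draws of zero flowers are resampled.
The symmetric-tail reading is a design choice: the constraint as stated (95%
coverage of an interval) underdetermines two parameters, and equal tails is
the only symmetric two-equation closure. Under this exposure and a Poisson
visit distribution at the baseline rate, about 13.2% of simulated events have
zero visits (the reference design reports about 12.7%, a discrepancy we
attribute to unstated details of its tail adjustment; the package reports
what its own stated world produces).

**Covariate.** Four effect types, always through a log link on the expected
per-flower rate λ with baseline λ₀ = 0.02:

| effect type        | covariate design                          | formula                      | default n |
|--------------------|-------------------------------------------|------------------------------|-----------|
| fixed categorical  | Bernoulli, P(x=1)=0.6                     | log λ = log λ₀ + βx          | 30        |
| fixed linear       | x ~ Uniform(0,1)                          | log λ = log λ₀ + βx          | 30        |
| random intercept   | 5 categories, traversed cyclically        | log λ = log λ₀ + ε_c, ε_c ~ N(0, σ²) | 75 (15/category) |
| random slope       | 5 categories × equally spaced x on [0,1]  | log λ = log λ₀ + b_c x, b_c ~ N(0, σ²) | 300 (60/category) |

Random-effect draws are made once per category per dataset, not per row. The
continuous covariate range is taken as the unit interval, so β is directly
the log-rate change across the observed gradient. λ₀ = 0.02 visits per
flower per period is deliberately low so that zero counts are common even
with large exposures.

**Visits.** Counts are drawn with mean `N·λ` from one of three families:
Poisson; negative binomial with overdispersion `k = 10`
(variance `m + m²/k`); or lognormal-Poisson with log-scale sd 0.36, i.e.
Poisson with a latent lognormal rate multiplier. The multiplier uses the
mean-one convention `ε ~ N(−sd²/2, sd²)` so the marginal mean stays `N·λ`;
a median-one convention is available via
`count_family(..., lognormal_mean_one = FALSE)`. The lognormal-Poisson has
no closed-form pmf; `count_logpmf()` integrates the latent multiplier with
40-node Gauss–Hermite quadrature (node count configurable), which the test
suite checks against adaptive quadrature to 1e-7.

The frequency dataset is the deterministic projection `freq = visits/N` with
the exposure column dropped.

## The analysis models

Count data are fit with six models: Poisson, negative binomial and
zero-inflated negative binomial, each with and without the (known-in-advance)
effect structure, all with `log(flowers)` as offset. The zero-inflated
negative binomial is deliberately a model *not* present among the generating
families, just as the lognormal-Poisson generator is absent from the analysis
set — a planned asymmetry probing robustness to model misspecification. Its
inflation probability is covariate-free, the simplest reading of the model's
name.

Frequency data are fit with three zero-inflated gamma models: no effect, an
effect on the gamma expectancy μ only, and an effect on both μ and the
zero-inflation. The zero-inflation probability is linked to the expectancy
through a responsiveness parameter g. The package's default link is

p₀ = 1 / (1 + e^g μ),

which *decreases* in μ: the fewer visits expected, the likelier an exact
zero. The two published statements of this link disagree — the printed
formula `p₀ = e^g μ/(1+e^g μ)` increases in μ, while the stated intent is
that zero-inflation rises as the expectancy falls. Both orientations are
implemented (`form`/`p0_form = "literal"` selects the printed one); the
default follows the stated intent. In the `mean_and_zi` model the covariate
additionally shifts the logit of p₀ — the raw covariate for fixed effects,
the category's latent term for random effects — one extra parameter
(`beta_zi`) in either case. The exact parameterisation used by the original
frequency models is not recoverable from the available text; this one is the
package's documented choice.

## Inference and model choice

Every model is estimated by adaptive random-walk Metropolis on the
unconstrained scale (log for positive parameters, logit for probabilities):
joint Gaussian proposals, global step size adapted toward 0.234 acceptance in
windows of 50 iterations during burn-in, per-coordinate scales tracked from
the chain history, adaptation frozen after burn-in. Defaults: 2 chains,
10,000 iterations, 50% burn-in (`run_mcmc()`); convergence is flagged by the
Gelman–Rubin factor (< 1.1 per parameter). Latent random effects are sampled
as parameters rather than marginalised by quadrature.

Model comparison uses the Bayesian model likelihood P(D|M), estimated by
importance sampling over the MCMC output: a multivariate t with 5 degrees of
freedom (configurable) is moment-matched to the pooled posterior draws, and
`log P(D|M)` is the log-mean of prior × likelihood over the importance
density, with a delta-method Monte Carlo standard error and an
effective-sample-size degeneracy flag. Because the latents are coordinates of
the posterior, the importance integral marginalises them. The estimator is
validated in the test suite against the closed-form Poisson–gamma conjugate
marginal (20 datasets, 3 MC SEs).

Priors are "wide but informative", centred at the simulation's operating
point, and are this package's own substitutes (the reference priors are not
available): log λ₀ ~ N(log 0.02, 2); β ~ N(0, 2); random-effect scale σ ~
half-N(1); log k ~ N(log 10, 2); logit p_zi ~ N(−2, 2); log shape ~ N(0, 2);
g ~ N(0, 3); beta_zi ~ N(0, 2). All are overridable through
`default_priors()`. Absolute false-positive rates are sensitive to prior
width (wider effect priors mean a stronger Occam penalty and fewer false
positives); with these substitutes the package's type-I rates run a few
percentage points above the reference values, while every ordering and ratio
contrast reproduces.

An effect is declared found when the best effect model beats the best
no-effect model by a Bayes factor above the threshold (strictly; ties count
as no effect, a measure-zero conservative choice). Threshold 1 is the
equal-prior highest-BML rule; sweeping the threshold traces the ROC curve.
AUC is computed as the Mann–Whitney ranking probability (ties one half),
which provably equals — and in the tests is checked against — the
trapezoidal area under the swept curve.

## The power study

`calibrate_effect_strength()` adjusts the effect magnitude so the
count-data analysis misses the effect about 10% of the time, making the
comparison non-trivial; FN is monotone decreasing in strength, so the search
brackets and bisects, using common random numbers (one master seed shared by
all evaluations) so Monte Carlo noise cannot break monotonicity.
`run_batch()` then simulates and analyses replicate datasets under both
representations; `error_rates()`, `roc_curve()` and `sample_size_search()`
tabulate the comparison. Per-replicate seeds derive deterministically from
the master seed, so batches are bit-reproducible and shardable by seed range.

## Scale: what the desk-size defaults do and do not establish

The reference design is 4 effect types × 3 distributions × 2 (effect/null) ×
10,000 datasets, with 9 MCMC fits per dataset — cluster scale. The package
defaults are deliberately smaller: 500 datasets per batch, 2 × 4,000 MCMC
iterations in `run_batch()` (2 × 2,000 and 600 importance draws in the
acceptance tests), with binomial standard errors reported alongside every
rate. At 500 datasets a 10% rate carries a ±1.3pp standard error; contrasts
of a few percentage points are resolvable, third-digit agreement is not and
is never asserted. The generator emulates variable exposure, low baseline
rates and the three stated count families; it does not emulate temporal or
spatial autocorrelation, varying observation times, or observer error — a
green suite says the machinery reproduces the stated world's contrasts, not
that real field data behave this way.

## Numerical choices and degenerate inputs

* Exposure solver: Nelder–Mead on the squared tail-probability residuals with
  a 1e-8 convergence gate and a 1e-3 coverage invariant check.
* Truncated-support pmf sums, density normalisation (point mass + quadrature
  of the continuous part) and sampler moments are property-tested.
* `estimate_log_bml()` adds a 1e-8 ridge to the moment-matched covariance;
  degenerate importance weights (ESS below 50) raise a warning and a flag
  rather than failing.
* Zero-probability models (`p_zi = 0`, `sd = 0`) collapse exactly to their
  nested families; the likelihood evaluates them without special-casing.
* Batch replicates that error are flagged (`ok_count`/`ok_freq = FALSE`) and
  excluded from rate denominators, never silently dropped.
* Calibration tolerance defaults to two binomial standard errors of the
  batch estimate at the target rate, the resolution limit of the batch.

## Known limitations

* Absolute type-I/type-II levels depend on the substitute priors; only
  orderings, ratios and AUC contrasts should be compared across
  implementations.
* The zero-inflated-gamma `mean_and_zi` parameterisation is one defensible
  choice among several.
* Marginalising latent random effects through the importance integral (up to
  7 extra dimensions) is noisier than quadrature marginalisation would be;
  the BML MC standard errors make that noise visible.
* No parallel execution; shard large runs by seed range instead.
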