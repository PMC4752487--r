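# countpower

Statistical power of **count-data analyses versus derived-frequency
analyses** of visitation data.

## The problem

In pollination ecology (and in any field that divides one count by another),
flower visitation is usually analysed as a frequency — visits per flower per
unit time — although what was actually measured is a count of visits over a
known, highly variable exposure (the number of flowers observed). The
frequency collapses 100 visits in 200 flowers and 2 visits in 4 flowers into
the same value 0.5, discarding the exposure and with it most of the
information about measurement precision. A count model with the log-exposure
as an offset,

```
visits_i ~ CountFamily(mean = flowers_i * λ(x_i)),   log λ(x) = log λ₀ + βx,
```

keeps that information; a model for the derived ratio — here a zero-inflated
gamma with the point mass at zero linked to the expectancy μ through
p₀ = 1/(1 + e^g μ) — cannot. `countpower` measures exactly how much
detection power the ratio representation costs, for ecologists planning
visitation studies and for statisticians interested in exposure handling.

It simulates datasets under four effect types (fixed categorical, fixed
linear, random intercept, random slope) and three generating count
distributions (Poisson, negative binomial `k = 10`, lognormal-Poisson
`sd = 0.36`) with exposure drawn from a negative binomial holding 95% of its
mass on [10, 1000]; fits six count models and three frequency models per
dataset by adaptive Metropolis MCMC; scores models with importance-sampled
Bayesian model likelihoods (BML); and declares an effect found when the best
effect model beats the best no-effect model by a Bayes-factor threshold.
Batch drivers tabulate false-negative/false-positive rates, ROC curves with
AUC, calibrate effect strengths to a 10% false-negative target, and search
for the sample size the frequency analysis needs to match the count
analysis.

## Worked example

Simulate one dataset with a binary effect (baseline rate λ₀ = 0.02 visits
per flower, effect β = 0.8 on the log scale), then analyse it both ways:

```r
library(countpower)
exposure <- solve_exposure_params()          # NB with 95% mass on [10, 1000]
eff <- effect_spec("fixed_categorical", lambda0 = 0.02, strength = 0.8)
ds <- simulate_dataset(count_family("poisson"), eff, exposure, n = 30, seed = 1)
head(ds, 4)
#>   flowers category x visits
#> 1      66       NA 1      4
#> 2     523       NA 0      8
#> 3     402       NA 0      6
#> 4     287       NA 0      4

res_count <- analyze_dataset(ds, seed = 1)   # six count models, log(flowers) offset
round(res_count$log_bml, 2)
#>       poisson_null     poisson_effect      negbinom_null    negbinom_effect
#>             -87.94             -70.85             -80.33             -71.54
#>   zi_negbinom_null zi_negbinom_effect
#>             -81.89             -73.11

fr <- to_frequency(ds)                       # visits/flowers, exposure dropped
res_freq <- analyze_dataset(fr, seed = 1)    # three zero-inflated gamma models
round(res_freq$log_bml, 2)
#>    zi_gamma_null    zi_gamma_mean zi_gamma_mean_zi
#>            64.28            72.10            72.04

c(count = res_count$score, freq = res_freq$score)
#>    count     freq
#> 9.477477 7.818394
```

Both analyses find this (strong) effect — `score` is the log Bayes factor of
the best effect model over the best no-effect model, and both exceed
`log(1) = 0` — but the count analysis finds it with more evidence (9.5 vs
7.8 nats). Over hundreds of replicates at a calibrated ~10% count-data
false-negative rate, the frequency analysis misses the effect roughly 2–3
times as often, and its AUC is consistently lower; run the batch drivers
(`run_batch()`, `error_rates()`, `roc_curve()`) or the configured experiment
(`run_experiment()`, `summarize_experiment()`, or
`inst/cli/countpower.R run --config cfg.json --out results/`) to reproduce
those tables.

## Package layout

- `R/distributions.R` — pmf/density/samplers for every generating and
  analysis family, including the zero-inflated gamma with expectancy-linked
  zero-inflation.
- `R/simulate.R` — exposure solver and dataset generators; CSV + JSON
  sidecar I/O.
- `R/inference.R` — model specs, priors, MCMC (Rcpp core in
  `src/mcmc.cpp`), importance-sampled BML, model selection.
- `R/power_study.R` — batches, error rates, calibration, ROC/AUC,
  sample-size search.
- `R/cli_report.R` — experiment configs, result bundles, summary tables.
- `vignettes/count-vs-frequency.Rmd` — the methods vignette: model
  assumptions, parameter meanings, numerical choices, limitations.
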