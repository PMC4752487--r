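#' Scenario: one cell of the simulation study
#'
#' A scenario fixes the effect type, the generating count distribution, the
#' dataset size and the effect strength; together with a master seed it fully
#' determines a batch of simulated datasets and their analyses.
#'
#' @param effect_type effect type as in [effect_spec()].
#' @param family generating [count_family()].
#' @param strength effect strength (beta or sigma; see [effect_spec()]).
#' @param lambda0 baseline visits per flower (default 0.02).
#' @param n_rows rows per dataset (default [default_n_rows()]).
#' @param n_categories categories for random effects.
#' @param exposure exposure spec (default [solve_exposure_params()]).
#' @return object of class `scenario`.
#' @export
scenario <- function(effect_type, family, strength, lambda0 = 0.02,
                     n_rows = default_n_rows(effect_type), n_categories = 5L,
                     exposure = solve_exposure_params()) {
  stopifnot(inherits(family, "count_family"),
            inherits(exposure, "exposure_spec"))
  structure(list(effect_type = effect_type, family = family,
                 strength = strength, lambda0 = lambda0,
                 n_rows = as.integer(n_rows),
                 n_categories = as.integer(n_categories), exposure = exposure),
            class = "scenario")
}

# deterministic per-replicate seed, kept within the 32-bit integer range
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 16807) %% 2147483563) + 1L
}

#' Simulate and analyse a batch of datasets
#'
#' For each replicate: simulate a count dataset under the scenario, derive
#' its frequency representation, run the count and/or frequency model sets,
#' and record the [detect_effect()] scores. Per-replicate seeds are derived
#' deterministically from `master_seed`, so a batch is exactly reproducible.
#' Individual replicate failures are flagged, not fatal.
#'
#' @param scn a [scenario()].
#' @param n_datasets number of replicates.
#' @param effect_present simulate with (`TRUE`) or without (`FALSE`) the
#'   effect.
#' @param master_seed integer master seed.
#' @param data_kinds which analyses to run: subset of
#'   `c("count", "frequency")`.
#' @param priors prior list.
#' @param n_iter,n_chains,n_draws per-model MCMC/importance-sampling sizes.
#'   The defaults (2 x 4000 iterations, 1000 importance draws) are the
#'   desk-scale setting used throughout the package's own experiments.
#' @return object of class `batch_result`: data.frame with columns
#'   `replicate`, `seed`, `truth`, `score_count`, `score_freq`, `ok_count`,
#'   `ok_freq` plus the scenario as an attribute.
#' @export
run_batch <- function(scn, n_datasets, effect_present, master_seed,
                      data_kinds = c("count", "frequency"),
                      priors = default_priors(), n_iter = 4000L,
                      n_chains = 2L, n_draws = 1000L) {
  stopifnot(inherits(scn, "scenario"))
  data_kinds <- match.arg(data_kinds, several.ok = TRUE)
  n_datasets <- as.integer(n_datasets)
  out <- data.frame(replicate = seq_len(n_datasets),
                    seed = if (n_datasets) vapply(seq_len(n_datasets),
                      function(i) derive_seed(master_seed, i), 0L) else integer(),
                    truth = rep(isTRUE(effect_present), n_datasets),
                    score_count = rep(NA_real_, n_datasets),
                    score_freq = rep(NA_real_, n_datasets),
                    ok_count = rep(NA, n_datasets),
                    ok_freq = rep(NA, n_datasets))
  es <- effect_spec(scn$effect_type, scn$lambda0, scn$strength,
                    scn$n_categories, effect_present)
  for (i in seq_len(n_datasets)) {
    si <- out$seed[i]
    ds <- simulate_dataset(scn$family, es, scn$exposure, scn$n_rows, seed = si)
    if ("count" %in% data_kinds) {
      r <- tryCatch(analyze_dataset(ds, scn$effect_type, priors, n_iter,
                                    n_chains, n_draws, seed = si),
                    error = function(e) NULL)
      if (!is.null(r)) {
        out$score_count[i] <- r$score
        out$ok_count[i] <- all(r$converged) && !any(r$degenerate)
      } else out$ok_count[i] <- FALSE
    }
    if ("frequency" %in% data_kinds) {
      fr <- to_frequency(ds)
      r <- tryCatch(analyze_dataset(fr, scn$effect_type, priors, n_iter,
                                    n_chains, n_draws, seed = si + 1L),
                    error = function(e) NULL)
      if (!is.null(r)) {
        out$score_freq[i] <- r$score
        out$ok_freq[i] <- all(r$converged) && !any(r$degenerate)
      } else out$ok_freq[i] <- FALSE
    }
  }
  structure(out, scenario = scn, effect_present = isTRUE(effect_present),
            master_seed = master_seed,
            class = c("batch_result", "data.frame"))
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Type-I and type-II error rates of a scenario
#'
#' The false-negative rate is the fraction of effect datasets whose score
#' fails the threshold; the false-positive rate is the fraction of null
#' datasets whose score passes it — computed separately for the count and
#' frequency analyses. Binomial standard errors accompany every rate.
#'
#' @param effect_batch,null_batch [run_batch()] results simulated with and
#'   without the effect.
#' @param threshold Bayes-factor threshold (default 1).
#' @return data.frame with one row per data kind: columns `data_kind`, `fn`,
#'   `fp`, `fn_se`, `fp_se`, `n_effect`, `n_null`.
#' @export
error_rates <- function(effect_batch, null_batch, threshold = 1) {
  stopifnot(inherits(effect_batch, "batch_result"),
            inherits(null_batch, "batch_result"))
  if (nrow(effect_batch) == 0 || nrow(null_batch) == 0)
    stop("empty batch")
  lt <- log(threshold)
  one <- function(kind) {
    se_col <- paste0("score_", kind)
    es <- effect_batch[[se_col]]
    ns <- null_batch[[se_col]]
    es <- es[!is.na(es)]; ns <- ns[!is.na(ns)]
    fn <- mean(!(es > lt))
    fp <- mean(ns > lt)
    data.frame(data_kind = kind, fn = fn, fp = fp,
               fn_se = binom_se(fn, length(es)), fp_se = binom_se(fp, length(ns)),
               n_effect = length(es), n_null = length(ns))
  }
  kinds <- c("count", "frequency")[c(any(!is.na(effect_batch$score_count)),
                                     any(!is.na(effect_batch$score_freq)))]
  do.call(rbind, lapply(sub("frequency", "freq", kinds), one))
}

#' Calibrate the effect strength to a target false-negative rate
#'
#' Searches the effect strength so that the count-data analysis misses the
#' effect in about `target_fn` of replicates (the study's operating point is
#' 10%). The false-negative rate decreases monotonically in strength, so the
#' search first expands a bracket and then bisects, evaluating each candidate
#' with a fresh [run_batch()] of the count analysis under common random
#' numbers (same master seed for all evaluations, to stop Monte Carlo noise
#' from breaking monotonicity).
#'
#' @param scn a [scenario()]; its `strength` is used as the starting guess
#'   (or 0.5 if zero).
#' @param target_fn target false-negative probability (default 0.1).
#' @param batch_size replicates per evaluation (default 200).
#' @param tolerance acceptable |FN - target|; defaults to twice the binomial
#'   standard error of the batch estimate at the target.
#' @param max_iter maximum bisection steps (default 12).
#' @param master_seed seed shared by all evaluations.
#' @param ... further arguments passed to [run_batch()] (`n_iter`, ...).
#' @return list with `strength`, `fn` (its estimated FN), `trace`
#'   (data.frame of evaluated points), and the final `scenario`.
#' @export
calibrate_effect_strength <- function(scn, target_fn = 0.1, batch_size = 200L,
                                      tolerance = NULL, max_iter = 12L,
                                      master_seed = 1L, ...) {
  stopifnot(target_fn > 0, target_fn < 1)
  if (is.null(tolerance))
    tolerance <- 2 * binom_se(target_fn, batch_size)
  trace <- data.frame(strength = numeric(), fn = numeric())
  eval_fn <- function(s) {
    sc <- scn; sc$strength <- s
    b <- run_batch(sc, batch_size, TRUE, master_seed, data_kinds = "count", ...)
    fn <- mean(!(b$score_count[!is.na(b$score_count)] > 0))
    trace <<- rbind(trace, data.frame(strength = s, fn = fn))
    fn
  }
  lo <- 0; hi <- if (scn$strength > 0) scn$strength else 0.5
  fn_hi <- eval_fn(hi)
  it <- 0
  while (fn_hi > target_fn && it < max_iter) { # too weak: expand upwards
    lo <- hi; hi <- hi * 2; fn_hi <- eval_fn(hi); it <- it + 1
  }
  if (fn_hi > target_fn)
    stop("calibration failed to bracket the target; trace:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"))
  if (abs(fn_hi - target_fn) <= tolerance)
    return(list(strength = hi, fn = fn_hi, trace = trace,
                scenario = { s <- scn; s$strength <- hi; s }))
  best <- c(hi, fn_hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fn_mid <- eval_fn(mid)
    if (abs(fn_mid - target_fn) < abs(best[2] - target_fn))
      best <- c(mid, fn_mid)
    if (abs(fn_mid - target_fn) <= tolerance) break
    if (fn_mid > target_fn) lo <- mid else hi <- mid
  }
  list(strength = best[1], fn = best[2], trace = trace,
       scenario = { s <- scn; s$strength <- best[1]; s })
}

#' ROC curve and AUC from effect and null scores
#'
#' Sweeps the declaration threshold over every observed score and records the
#' (false-positive rate, true-positive rate) pairs. The AUC is computed as
#' the Mann-Whitney probability that a random effect dataset outscores a
#' random null dataset (ties counting one half), which equals the trapezoidal
#' area under the swept step curve.
#'
#' @param effect_scores scores of datasets simulated with the effect.
#' @param null_scores scores of datasets simulated without it.
#' @return object of class `roc_curve`: list with `points` (data.frame
#'   `fpr`, `tpr`, `threshold` on the log-Bayes-factor scale) and `auc`.
#' @export
roc_curve <- function(effect_scores, null_scores) {
  effect_scores <- effect_scores[!is.na(effect_scores)]
  null_scores <- null_scores[!is.na(null_scores)]
  if (!length(effect_scores) || !length(null_scores))
    stop("both score vectors must be nonempty")
  thr <- c(Inf, sort(unique(c(effect_scores, null_scores)),
                     decreasing = TRUE), -Inf)
  pts <- data.frame(threshold = thr,
                    fpr = vapply(thr, function(t) mean(null_scores >= t), 0),
                    tpr = vapply(thr, function(t) mean(effect_scores >= t), 0))
  # Mann-Whitney with ties at one half
  r <- rank(c(effect_scores, null_scores))
  n1 <- length(effect_scores); n0 <- length(null_scores)
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Trapezoidal area under a ROC curve
#'
#' Independent of the Mann-Whitney computation in [roc_curve()]; the two must
#' agree to numerical precision.
#' @param roc a `roc_curve` object.
#' @return scalar area.
#' @export
roc_trapezoid_area <- function(roc) {
  p <- roc$points[order(roc$points$fpr, roc$points$tpr), ]
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " points, AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Sample size needed by the frequency analysis
#'
#' Holding the (already calibrated) effect strength fixed, searches the
#' number of rows per dataset at which the chosen analysis attains the target
#' false-negative rate — the experiment quantifying how much more data the
#' frequency representation needs than the count representation. FN is
#' nonincreasing in `n`, so the search is bisection over the integer bracket
#' under common random numbers.
#'
#' @param scn a [scenario()] carrying the calibrated strength.
#' @param target_fn target false-negative rate (default 0.1).
#' @param data_kind `"frequency"` (default) or `"count"`.
#' @param bracket integer c(lower, upper) for the row count.
#' @param batch_size replicates per evaluation.
#' @param tolerance acceptable |FN - target| (default 2 binomial SE).
#' @param master_seed seed shared by all evaluations.
#' @param ... passed to [run_batch()].
#' @return list with `n` (rows needed), `fn`, and `trace`.
#' @export
sample_size_search <- function(scn, target_fn = 0.1, data_kind = "frequency",
                               bracket = c(scn$n_rows, 8L * scn$n_rows),
                               batch_size = 200L, tolerance = NULL,
                               master_seed = 1L, ...) {
  if (is.null(tolerance))
    tolerance <- 2 * binom_se(target_fn, batch_size)
  col <- if (data_kind == "frequency") "score_freq" else "score_count"
  trace <- data.frame(n = integer(), fn = numeric())
  eval_fn <- function(n) {
    sc <- scn; sc$n_rows <- as.integer(n)
    b <- run_batch(sc, batch_size, TRUE, master_seed, data_kinds = data_kind, ...)
    s <- b[[col]]
    fn <- mean(!(s[!is.na(s)] > 0))
    trace <<- rbind(trace, data.frame(n = as.integer(n), fn = fn))
    fn
  }
  lo <- bracket[1]; hi <- bracket[2]
  fn_lo <- eval_fn(lo)
  if (abs(fn_lo - target_fn) <= tolerance)
    return(list(n = lo, fn = fn_lo, trace = trace))
  if (fn_lo < target_fn)
    stop("target already met at the lower bracket (FN = ", fn_lo, ")")
  fn_hi <- eval_fn(hi)
  if (fn_hi > target_fn + tolerance)
    stop("target unattainable within the bracket (FN at n = ", hi, " is ",
         fn_hi, ")")
  best <- c(hi, fn_hi)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    fn_mid <- eval_fn(mid)
    if (abs(fn_mid - target_fn) < abs(best[2] - target_fn))
      best <- c(mid, fn_mid)
    if (abs(fn_mid - target_fn) <= tolerance) break
    if (fn_mid > target_fn) lo <- mid else hi <- mid
  }
  list(n = as.integer(best[1]), fn = best[2], trace = trace)
}
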