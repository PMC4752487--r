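test_that("solve_exposure_params satisfies the coverage invariant", {
  ex <- exposure_fixture()
  got <- pnbinom(ex$upper, size = ex$nb_size, mu = ex$nb_mean) -
    pnbinom(ex$lower - 1, size = ex$nb_size, mu = ex$nb_mean)
  expect_lt(abs(got - 0.95), 1e-3)
  # the two tails are symmetric by construction
  expect_lt(abs(pnbinom(9, size = ex$nb_size, mu = ex$nb_mean) - 0.025), 1e-4)
  expect_lt(abs(pnbinom(1000, size = ex$nb_size, mu = ex$nb_mean,
                        lower.tail = FALSE) - 0.025), 1e-4)
})

test_that("solve_exposure_params copes with very loose constraints", {
  ex <- solve_exposure_params(1, 1e6, 0.9999)
  got <- pnbinom(ex$upper, size = ex$nb_size, mu = ex$nb_mean) -
    pnbinom(ex$lower - 1, size = ex$nb_size, mu = ex$nb_mean)
  expect_lt(abs(got - 0.9999), 1e-3)
})

test_that("sample_exposure respects the resampling and coverage contracts", {
  set.seed(2002)
  ex <- exposure_fixture()
  n <- 1e5
  draws <- sample_exposure(n, ex)
  expect_true(all(draws >= 1))
  frac <- mean(draws >= 10 & draws <= 1000)
  expect_lt(abs(frac - 0.95), 0.005)
  # zero-truncated NB mean
  p0 <- dnbinom(0, size = ex$nb_size, mu = ex$nb_mean)
  m_trunc <- ex$nb_mean / (1 - p0)
  expect_lt(abs(mean(draws) - m_trunc), 4 * sd(draws) / sqrt(n))
})

test_that("make_covariates builds each design correctly", {
  set.seed(3)
  x <- make_covariates("fixed_categorical", 1e5)$x
  expect_true(all(x %in% c(0, 1)))
  expect_lt(abs(mean(x) - 0.6), 4 * sqrt(0.6 * 0.4 / 1e5))
  x <- make_covariates("fixed_linear", 1e4)$x
  expect_true(all(x >= 0 & x <= 1))
  ri <- make_covariates("random_intercept", 75)
  expect_equal(as.integer(table(ri$category)), rep(15L, 5))
  rs <- make_covariates("random_slope", 300)
  expect_equal(as.integer(table(rs$category)), rep(60L, 5))
  # systematic grid, equally spaced on [0, 1] within each category
  for (k in 1:5)
    expect_equal(rs$x[rs$category == k], seq(0, 1, length.out = 60))
  expect_error(make_covariates("random_intercept", 76), "divisible")
})

test_that("effect_rate implements the log-link formulas", {
  cov1 <- data.frame(category = NA, x = c(0, 1, 0.5))
  es <- effect_spec("fixed_linear", strength = 0.5)
  expect_equal(effect_rate(es, cov1), 0.02 * exp(0.5 * c(0, 1, 0.5)))
  expect_equal(effect_rate(es, cov1)[2], 0.032974425, tolerance = 1e-6)
  # null effect: lambda0 everywhere regardless of strength
  es0 <- effect_spec("fixed_linear", strength = 5, effect_present = FALSE)
  expect_equal(effect_rate(es0, cov1), rep(0.02, 3))
  # categorical: x = 0 gives exactly lambda0
  esc <- effect_spec("fixed_categorical", strength = 2)
  expect_equal(effect_rate(esc, data.frame(category = NA, x = 0)), 0.02)
  # random effects need their per-category draws
  esr <- effect_spec("random_intercept", strength = 1)
  covr <- data.frame(category = c(1, 3), x = NA)
  expect_error(effect_rate(esr, covr), "random draws")
  expect_equal(effect_rate(esr, covr, random_draws = c(0.1, 0, -0.2, 0, 0)),
               0.02 * exp(c(0.1, -0.2)))
})

test_that("random-effect draws have the specified spread across datasets", {
  set.seed(11)
  sigma <- 0.7
  es <- effect_spec("random_intercept", strength = sigma)
  draws <- replicate(1000, draw_random_effects(es))
  expect_lt(abs(sd(draws) - sigma), 0.05)
  expect_null(draw_random_effects(effect_spec("fixed_linear", strength = 1)))
})

test_that("simulate_dataset is deterministic and honours the null model", {
  ex <- exposure_fixture()
  a <- small_count_ds(seed = 5)
  b <- small_count_ds(seed = 5)
  expect_identical(a$visits, b$visits)
  expect_identical(a$flowers, b$flowers)
  expect_false(identical(a$visits, small_count_ds(seed = 6)$visits))
  # default sizes per effect type
  expect_equal(nrow(a), 30)
  es <- effect_spec("random_intercept", strength = 0.5)
  expect_equal(nrow(simulate_dataset(count_family("poisson"), es, ex, seed = 1)), 75)
  # null Poisson rows: mean visits/flower ~ lambda0 over many rows
  es0 <- effect_spec("fixed_categorical", effect_present = FALSE)
  big <- simulate_dataset(count_family("poisson"), es0, ex, n = 10000, seed = 8)
  r <- big$visits / big$flowers
  expect_lt(abs(mean(r) - 0.02), 4 * sd(r) / sqrt(nrow(big)))
})

test_that("null datasets from all three families share the baseline rate", {
  ex <- exposure_fixture()
  es0 <- effect_spec("fixed_categorical", effect_present = FALSE)
  for (fam in list(count_family("poisson"), count_family("negbinom", k = 10),
                   count_family("lognormal_poisson", sd = 0.36))) {
    ds <- simulate_dataset(fam, es0, ex, n = 5000, seed = 21)
    r <- ds$visits / ds$flowers
    expect_lt(abs(mean(r) - 0.02), 4 * sd(r) / sqrt(nrow(ds)))
  }
})

test_that("to_frequency is the stated lossy projection", {
  ds <- small_count_ds(seed = 9)
  fr <- to_frequency(ds)
  expect_s3_class(fr, "frequency_dataset")
  expect_equal(fr$freq, ds$visits / ds$flowers)
  expect_null(fr$flowers)
  expect_identical(fr$freq == 0, ds$visits == 0)
  # the motivating identity: different counts, same frequency
  d2 <- data.frame(flowers = c(200L, 4L), category = NA, x = c(0, 0),
                   visits = c(100L, 2L))
  class(d2) <- c("count_dataset", "data.frame")
  expect_equal(to_frequency(d2)$freq, c(0.5, 0.5))
  # exact round trip through the retained exposure
  expect_identical(as.integer(round(fr$freq * ds$flowers)), ds$visits)
  # same seed => same frequencies (deterministic projection)
  expect_equal(to_frequency(small_count_ds(seed = 9))$freq, fr$freq)
})

test_that("datasets survive a CSV round trip with metadata", {
  ds <- small_count_ds(seed = 13)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_dataset(ds, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_equal(attr(back, "effect_spec")$strength,
               attr(ds, "effect_spec")$strength)
  expect_equal(attr(back, "seed"), 13)
  fr <- to_frequency(ds)
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path2, paste0(path2, ".json"))), add = TRUE)
  write_dataset(fr, path2)
  expect_equal(read_dataset(path2)$freq, fr$freq)
})
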