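# Short-term PM-mortality association: spline basis, quasi-Poisson
# IRLS, df selection, RR per increment, random-effects pooling.

make_ts <- function(n, beta = 0.002, mu0 = 5, seed = 1, seasonal = 0) {
  cfg <- scenario_config(seed = seed, years = 2013:2015,
                         base_level = c(coastal = 28),
                         death_seasonal_amplitude = seasonal)
  full <- gen_pm10_series(cfg, thin = FALSE)
  tz <- full$truth[full$truth$zone == "coastal", ][seq_len(n), ]
  cfg$true_beta <- beta; cfg$mu0 <- mu0
  gen_health_counts(cfg, tz$pm10, tz$date)$series
}

test_that("time basis has df centered columns; df=1 is a linear trend", {
  dates <- seq(as.Date("2014-01-01"), by = "day", length.out = 300)
  for (df in c(1, 3, 6)) {
    b <- build_time_basis(dates, df)
    expect_identical(ncol(b), as.integer(df))
    expect_equal(colMeans(b), rep(0, df), tolerance = 1e-12)
  }
  b1 <- build_time_basis(dates, 1)
  expect_equal(abs(cor(b1[, 1], as.numeric(dates))), 1, tolerance = 1e-12)
  expect_error(build_time_basis(dates[1:5], 5), "smaller than")
  expect_error(build_time_basis(rev(dates), 3), "strictly increasing")
})

test_that("regression on the basis reproduces functions in its span", {
  dates <- seq(as.Date("2014-01-01"), by = "day", length.out = 200)
  b <- build_time_basis(dates, 5)
  set.seed(71)
  coefs <- rnorm(5)
  y <- 2 + drop(b %*% coefs)
  fit <- lm(y ~ b)
  expect_lt(max(abs(fitted(fit) - y)), 1e-6)
})

test_that("IRLS quasi-Poisson matches the reference GLM implementation", {
  s <- make_ts(600, seed = 72)
  f <- fit_quasipoisson(s, spline_df = 4)
  expect_true(f$converged)
  B <- build_time_basis(s$dates, 4)
  ref <- glm(s$deaths ~ s$pm + B, family = quasipoisson())
  expect_equal(unname(f$beta), unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
  # dispersion and SE carry the (tiny) difference between the two
  # implementations' stopping rules; coefficients are the tight contract
  expect_equal(f$dispersion, summary(ref)$dispersion, tolerance = 1e-3)
  expect_equal(unname(f$se_beta),
               unname(summary(ref)$coefficients[2, 2]), tolerance = 1e-3)
})

test_that("dispersion is near 1 for equidispersed Poisson data", {
  s <- make_ts(1000, seed = 73)
  f <- fit_quasipoisson(s, spline_df = 4)
  expect_gt(f$dispersion, 0.8)
  expect_lt(f$dispersion, 1.2)
})

test_that("the slope is recovered across replicates at the generator truth", {
  nrep <- 60
  betas <- vapply(seq_len(nrep), function(i) {
    fit_quasipoisson(make_ts(1000, seed = 700 + i), spline_df = 4)$beta
  }, numeric(1))
  mc_se <- sd(betas) / sqrt(nrep)
  expect_lt(abs(mean(betas) - 0.002), 2 * mc_se + 1e-12)
})

test_that("degenerate designs are refused loudly", {
  s <- make_ts(200, seed = 74)
  s$pm <- rep(30, length(s$pm))
  expect_error(fit_quasipoisson(s), "constant")
  short <- make_ts(60, seed = 74)
  expect_error(fit_quasipoisson(health_series("c", short$dates[1:20],
                                              short$deaths[1:20],
                                              short$pm[1:20])), "at least 50")
})

test_that("QAIC selection prefers small df without seasonality, larger with", {
  # no injected seasonality: smallest df wins most of the time
  hits <- vapply(1:40, function(i) {
    select_spline_df(make_ts(400, seed = 800 + i), c(1, 4, 8))$spline_df
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.8)
  # strong annual cycle: selection moves above the linear trend
  hits2 <- vapply(1:40, function(i) {
    select_spline_df(make_ts(730, seed = 900 + i, seasonal = 0.5),
                     c(1, 4, 8))$spline_df
  }, numeric(1))
  expect_gte(mean(hits2 > 1), 0.9)
  # a single-element grid is returned as-is
  expect_identical(select_spline_df(make_ts(300, seed = 75), 3)$spline_df, 3L)
})

test_that("RR per increment exponentiates the slope with Wald bounds", {
  f <- fit_quasipoisson(make_ts(600, seed = 76), spline_df = 2)
  f0 <- f; f0$beta <- 0
  expect_equal(rr_per_increment(f0, 25)$rr, 1)
  f1 <- f; f1$beta <- 0.001
  expect_equal(rr_per_increment(f1, 10)$rr, exp(0.01))
  r <- rr_per_increment(f, f$iqr)
  expect_true(r$ci_low < r$rr && r$rr < r$ci_high)
  # multiplicative in the increment
  expect_equal(rr_per_increment(f, 7)$rr * rr_per_increment(f, 5)$rr,
               rr_per_increment(f, 12)$rr, tolerance = 1e-12)
  expect_error(rr_per_increment(f, 0), "increment")
  fnc <- f; fnc$converged <- FALSE
  expect_error(rr_per_increment(fnc), "converge")
})

test_that("DerSimonian-Laird pooling satisfies its exact identities", {
  # k = 1: the input comes back, tau2 = 0
  p1 <- pool_random_effects(0.015, 0.004)
  expect_equal(p1$log_rr, 0.015)
  expect_equal(p1$se_log_rr, 0.004)
  expect_equal(p1$tau2, 0)
  # identical estimates: pooled equals them, tau2 = 0
  pid <- pool_random_effects(rep(0.01, 3), c(0.004, 0.006, 0.002))
  expect_equal(pid$log_rr, 0.01)
  expect_equal(pid$tau2, 0)
  # equal SEs: pooled is the arithmetic mean of the log-RRs
  y <- c(0.010, 0.022, 0.016)
  peq <- pool_random_effects(y, rep(0.003, 3))
  expect_equal(peq$log_rr, mean(y), tolerance = 1e-12)
  # tau2 = 0 (homogeneous data) reduces to fixed-effect pooling exactly
  y2 <- c(0.0100, 0.0101, 0.0099)
  se2 <- c(0.01, 0.02, 0.015)
  ph <- pool_random_effects(y2, se2)
  expect_equal(ph$tau2, 0)
  w <- 1 / se2^2
  expect_equal(ph$log_rr, sum(w * y2) / sum(w), tolerance = 1e-12)
  expect_equal(ph$se_log_rr, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_error(pool_random_effects(numeric(0), numeric(0)), "nothing to pool")
})

test_that("pooling agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(77)
  y <- rnorm(4, 0.015, 0.008)
  se <- runif(4, 0.003, 0.01)
  p <- pool_random_effects(y, se)
  m <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(p$log_rr, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(p$se_log_rr, m$se, tolerance = 1e-8)
})
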