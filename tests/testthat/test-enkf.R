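test_that("ensemble covariance matches the N-1 sample formula", {
  expect_equal(as.numeric(ensemble_covariance(c(1, 3))), 2)
  expect_equal(as.numeric(ensemble_covariance(c(0, 0, 3))), 3)
  expect_equal(as.numeric(ensemble_covariance(rep(2.5, 6))), 0)
  # multivariate case against the standard covariance estimator
  set.seed(14)
  ens <- matrix(rnorm(2 * 40), nrow = 2)
  expect_equal(ensemble_covariance(ens), unname(stats::cov(t(ens))),
               tolerance = 1e-12)
  expect_error(ensemble_covariance(1), "at least 2")
})

test_that("Kalman gain evaluates its closed form", {
  expect_equal(as.numeric(kalman_gain(1, 1, 1)), 0.5)
  expect_equal(as.numeric(kalman_gain(2, 1, 1)), 2 / 3, tolerance = 1e-12)
  # vanishing observation error gives full trust: K -> 1/h
  expect_equal(as.numeric(kalman_gain(1, 0, 2)), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(kalman_gain(1, 1e-14, 1)), 1, tolerance = 1e-10)
  expect_error(kalman_gain(0, 0, 1), "singular")
})

test_that("analysis update applies the member-wise correction", {
  expect_equal(analysis_update(2, 3, 0.5), 2.5)
  a_f <- c(1.5, 2.0, 2.5)
  expect_equal(analysis_update(a_f, c(3, 3, 3), 0), a_f)
  expect_equal(analysis_update(a_f, a_f, 0.7), a_f)  # zero innovation
  expect_equal(analysis_update(c(2, 4), c(3, 3), 0.5), c(2.5, 3.5))
  expect_equal(analysis_update(0.1, -5, 1), 0)       # floored at 0
  expect_error(analysis_update(c(1, 2), c(1, 2, 3), 0.5), "sizes differ")
})

test_that("scalar analysis keeps K in [0,1] and contracts the variance", {
  set.seed(31)
  for (i in 1:50) {
    a_c <- rexp(1); d_c <- rexp(1)
    k <- as.numeric(kalman_gain(a_c, d_c, 1))
    expect_gte(k, 0); expect_lte(k, 1)
    expect_lte((1 - k) * a_c, a_c)  # exact Kalman analysis variance
    # analysis mean lies between forecast mean and observation mean
    a_f <- rnorm(20, 2, 0.5); d_t <- rnorm(20, 3, 0.5)
    m <- mean(analysis_update(a_f, d_t, k))
    expect_gte(m, min(mean(a_f), mean(d_t)) - 1e-12)
    expect_lte(m, max(mean(a_f), mean(d_t)) + 1e-12)
  }
})

test_that("expansion parameter evaluates its formula and trigger rule", {
  r1 <- expansion_parameter(0.5, 10, 10, 10, 1)
  expect_equal(r1$e, 5); expect_true(r1$applied)
  r2 <- expansion_parameter(0.01, 100, 1, 5, 1)
  expect_equal(r2$e, 5e-4, tolerance = 1e-12); expect_false(r2$applied)
  # ratio exactly 4 is not strict inequality -> never applied
  r3 <- expansion_parameter(0.9, 10, 10, 4, 1)
  expect_equal(r3$e, 3.6, tolerance = 1e-12); expect_false(r3$applied)
  # E exactly 1 with ratio > 4 -> applied
  r4 <- expansion_parameter(0.5, 10, 4, 5, 1)
  expect_equal(r4$e, 1); expect_true(r4$applied)
  expect_warning(r5 <- expansion_parameter(0.5, 10, 5, 3, 0), "skipped")
  expect_false(r5$applied)
  expect_error(expansion_parameter(1.2, 10, 5, 3, 1), "strictly in")
  expect_error(expansion_parameter(0.5, 10, 11, 3, 1), "1..window")
})

test_that("assimilation runs are bit-identical under a fixed seed", {
  obs <- data.frame(day = c(3, 6, 9), lai = c(1, 2, 3))
  cfg <- enkf_config(n_members = 20, seed = 99)
  set.seed(1); members <- rnorm(20, 1, 0.1)
  r1 <- assimilate_window(members, 10, function(s, t) s * 1.05, obs, cfg)
  r2 <- assimilate_window(members, 10, function(s, t) s * 1.05, obs, cfg)
  expect_identical(r1, r2)
})

test_that("process noise widens the forecast ensemble", {
  set.seed(2); members <- rnorm(30, 2, 0.05)
  run <- function(sd_abs) {
    cfg <- enkf_config(n_members = 30, process_sd_abs = sd_abs,
                       process_sd_frac = 0, obs_sd_frac = 0.1, seed = 7)
    expect_warning(
      r <- assimilate_window(members, 15, function(s, t) s,
                             data.frame(day = integer(0), lai = numeric(0)),
                             cfg),
      "pure forecast")
    var(r$member_lai[15, ])
  }
  expect_gt(run(0.3), run(0))
})

test_that("noise-free observation at the forecast mean leaves the run unchanged", {
  members <- seq(0.5, 1.5, length.out = 21)  # mean exactly 1
  growth <- function(s, t) s  # identity: mean preserved
  obs <- data.frame(day = 1:10, lai = 1)
  cfg <- enkf_config(n_members = 21, process_sd_abs = 0, process_sd_frac = 0,
                     obs_sd_abs = 0, obs_sd_frac = 0, guard = FALSE, seed = 3)
  r <- assimilate_window(members, 10, growth, obs, cfg)
  expect_equal(r$analysis_mean, rep(1, 10), tolerance = 1e-12)
})

test_that("large-ensemble analysis means track the exact Kalman filter", {
  set.seed(42)
  n_days <- 20; q <- 0.09; r_var <- 0.25; m0 <- 5; p0 <- 1
  xx <- rnorm(1, m0, sqrt(p0)); y <- numeric(n_days)
  for (t in 1:n_days) { xx <- xx + rnorm(1, 0, sqrt(q))
                        y[t] <- xx + rnorm(1, 0, sqrt(r_var)) }
  kf <- kf_exact(y, m0, p0, q, r_var)
  set.seed(43); members <- rnorm(400, m0, sqrt(p0))
  cfg <- enkf_config(n_members = 400, process_sd_abs = sqrt(q),
                     process_sd_frac = 0, obs_sd_abs = sqrt(r_var),
                     obs_sd_frac = 0, guard = FALSE, seed = 44)
  res <- assimilate_window(members, n_days, function(s, t) s,
                           data.frame(day = 1:n_days, lai = y), cfg)
  expect_lt(max(abs(res$analysis_mean - kf$m) / abs(kf$m)), 0.1)
})

test_that("the divergence guard helps a collapsed ensemble follow drifting truth", {
  for (seed in 1:3)
    expect_lt(run_drift_toy(seed, guard = TRUE),
              run_drift_toy(seed, guard = FALSE))
})

test_that("crop-state assimilation tracks observations better than the free run", {
  w <- season_weather()
  truth <- truth_trajectory()
  obs <- data.frame(doy = w$doy, lai = truth$lai_green)
  p_biased <- crop_params(lue = 18)
  cfg <- enkf_config(n_members = 30, seed = 5)
  res <- assimilate_season(p_biased, w, default_san(), obs, cfg)
  free <- simulate_season(p_biased, w, default_san())$trajectory$lai_green
  expect_lt(rmse(res$analysis_mean, truth$lai_green),
            rmse(free, truth$lai_green))
  expect_true(all(res$analysis_mean >= 0))
})
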