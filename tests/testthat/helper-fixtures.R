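# shared fixtures and independent oracles, built in code at test time

default_san <- function() list(n_avail = 250, p_avail = 40, k_avail = 150)

# constant, deterministic weather for crop-model unit tests
const_weather <- function(n_days, doy0 = 140L, tmin = 12, tmax = 24,
                          radiation = 18, precip = 2) {
  data.frame(doy = doy0 + seq_len(n_days) - 1L, tmin = tmin, tmax = tmax,
             radiation = radiation, precip = precip)
}

# one season of generated weather + default-parameter truth, cached across
# test files (deterministic, seed fixed)
.fixture_cache <- new.env(parent = emptyenv())

season_weather <- function() {
  if (is.null(.fixture_cache$weather))
    .fixture_cache$weather <- gen_weather(160, 140, seed = 1)
  .fixture_cache$weather
}

truth_trajectory <- function() {
  if (is.null(.fixture_cache$truth))
    .fixture_cache$truth <- simulate_season(crop_params(), season_weather(),
                                            default_san())$trajectory
  .fixture_cache$truth
}

# full synthetic scene at the default study conditions (30 quadrats,
# three campaigns, six flights)
scene_fixture <- function(seed = 3) {
  key <- paste0("scene", seed)
  if (is.null(.fixture_cache[[key]])) {
    san <- gen_san(30, seed = 2)
    dat <- gen_truth_and_obs(crop_params(), season_weather(), san,
                             seed = seed)
    .fixture_cache[[key]] <- list(
      san = san,
      san_plot = data.frame(n_avail = mean(san$n_avail),
                            p_avail = mean(san$p_avail),
                            k_avail = mean(san$k_avail)),
      data = dat,
      truth_plot = stats::aggregate(lai_green ~ doy, dat$truth,
                                    mean)$lai_green)
  }
  .fixture_cache[[key]]
}

# exact closed-form Kalman filter for the scalar linear-Gaussian system
# x_t = x_{t-1} + N(0, q), y_t = x_t + N(0, r_var)
kf_exact <- function(y, m0, p0, q, r_var) {
  n <- length(y)
  m <- numeric(n); p <- numeric(n)
  mm <- m0; pp <- p0
  for (t in seq_len(n)) {
    pp <- pp + q
    k <- pp / (pp + r_var)
    mm <- mm + k * (y[t] - mm)
    pp <- (1 - k) * pp
    m[t] <- mm; p[t] <- pp
  }
  list(m = m, p = p)
}

# closed-form simple-regression oracle (normal equations)
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  a <- sxy / sxx
  list(a = a, b = mean(y) - a * mean(x), r = sxy / sqrt(sxx * syy))
}

# scalar toy assimilation with identity dynamics and a drifting truth;
# process noise zero so the ensemble collapses unless the guard intervenes
run_drift_toy <- function(seed, guard, n_days = 60, n_members = 40) {
  truth <- 1 + 0.08 * seq_len(n_days)
  obs <- data.frame(day = seq_len(n_days), lai = truth)
  set.seed(seed)
  members <- stats::rnorm(n_members, 1, 0.1)
  cfg <- enkf_config(n_members = n_members, process_sd_abs = 0,
                     process_sd_frac = 0, obs_sd_abs = 0, obs_sd_frac = 0.1,
                     guard = guard, seed = seed)
  res <- assimilate_window(members, n_days, function(s, t) s, obs, cfg)
  abs(res$analysis_mean[n_days] - truth[n_days])
}
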