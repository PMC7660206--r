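#' Sample covariance of a state ensemble
#'
#' For an ensemble `A = (x_1, ..., x_N)` (one column per member) the
#' covariance is `(A - Abar)(A - Abar)^T / (N - 1)`. A numeric vector is
#' treated as a scalar-state ensemble.
#'
#' @param ens numeric vector (scalar state) or matrix with one column per
#'   member.
#' @return covariance matrix (1 x 1 for scalar state).
#' @export
ensemble_covariance <- function(ens) {
  if (is.vector(ens)) ens <- matrix(ens, nrow = 1L)
  n <- ncol(ens)
  if (n < 2L) stop("need at least 2 ensemble members", call. = FALSE)
  dev <- ens - rowMeans(ens)
  (dev %*% t(dev)) / (n - 1)
}

#' Kalman gain
#'
#' `K = A_c H^T (H A_c H^T + D_c)^{-1}` with `A_c` the forecast-ensemble
#' covariance, `D_c` the observation-ensemble covariance and `H` the
#' observation operator. Scalars are accepted for the scalar-state case.
#'
#' @param a_c forecast covariance (matrix or scalar).
#' @param d_c observation covariance (matrix or scalar).
#' @param h observation operator (matrix or scalar, default identity 1).
#' @return the gain matrix (scalar state: 1 x 1).
#' @export
kalman_gain <- function(a_c, d_c, h = 1) {
  a_c <- as.matrix(a_c); d_c <- as.matrix(d_c); h <- as.matrix(h)
  innov <- h %*% a_c %*% t(h) + d_c
  if (rcond(innov) < 1e-14)
    stop(sprintf("innovation covariance numerically singular (rcond = %.3g)",
                 rcond(innov)), call. = FALSE)
  a_c %*% t(h) %*% solve(innov)
}

#' EnKF analysis update of a forecast ensemble
#'
#' Member-wise `A_a = A_f + K (D_t - H A_f)`; LAI components are floored at
#' 0 afterwards.
#'
#' @param a_f forecast ensemble (vector or matrix, one column per member).
#' @param d_t observed ensemble, conformable with `h %*% a_f`.
#' @param k Kalman gain.
#' @param h observation operator (default identity 1).
#' @return updated ensemble in the shape of `a_f`.
#' @export
analysis_update <- function(a_f, d_t, k, h = 1) {
  vec <- is.vector(a_f)
  if (vec) a_f <- matrix(a_f, nrow = 1L)
  if (is.vector(d_t)) d_t <- matrix(d_t, nrow = 1L)
  if (ncol(d_t) != ncol(a_f))
    stop("ensemble sizes differ between forecast and observation",
         call. = FALSE)
  k <- as.matrix(k); h <- as.matrix(h)
  a_a <- a_f + k %*% (d_t - h %*% a_f)
  a_a <- pmax(a_a, 0)
  if (vec) as.vector(a_a) else a_a
}

#' Expansion parameter guarding against filter divergence
#'
#' Filter divergence — the ensemble collapsing until observations are
#' effectively ignored — is countered by inflating the gain with
#' `E = R * N * sigma1^2 / (D * sigma2^2)`, where `R` is a uniform(0,1)
#' draw, `D` the total number of days in the assimilation stage, `N` the
#' current day index (1..D), `sigma1^2` the variance of the RS-based LAI
#' over days 1..N and `sigma2^2` the variance of the model (forecast-mean)
#' LAI over days 1..N. The inflation is applied only when
#' `sigma1^2/sigma2^2 > 4` (strictly) and `E >= 1`.
#'
#' @param r_draw uniform(0,1) random number.
#' @param window_days total days `D` of the assimilation stage.
#' @param day_index current day `N` (1 <= N <= D).
#' @param sigma1_sq variance of the RS-based LAI series so far.
#' @param sigma2_sq variance of the model LAI series so far.
#' @return list with `e` (the expansion value) and `applied` (logical).
#' @export
expansion_parameter <- function(r_draw, window_days, day_index,
                                sigma1_sq, sigma2_sq) {
  if (day_index < 1 || day_index > window_days)
    stop("`day_index` must lie in 1..window_days", call. = FALSE)
  if (r_draw <= 0 || r_draw >= 1)
    stop("`r_draw` must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(sigma2_sq) || sigma2_sq <= 0) {
    warning("sigma2^2 is zero or undefined; divergence guard skipped")
    return(list(e = NA_real_, applied = FALSE))
  }
  e <- r_draw * day_index * sigma1_sq / (window_days * sigma2_sq)
  list(e = e, applied = (sigma1_sq / sigma2_sq > 4) && (e >= 1))
}

#' EnKF configuration
#'
#' @param n_members ensemble size.
#' @param init_spread_frac lognormal sd of the multiplicative perturbation
#'   applied to the initial LAI when building a crop-state ensemble.
#' @param process_sd_abs,process_sd_frac additive forecast (process) noise:
#'   per member, sd = `process_sd_abs + process_sd_frac * LAI`.
#' @param obs_sd_abs,obs_sd_frac observation-ensemble perturbation: sd =
#'   `obs_sd_abs + obs_sd_frac * observed value`. The absolute floor keeps a
#'   reported LAI of 0 from acting as an infinitely precise observation.
#' @param guard enable the [expansion_parameter()] divergence guard.
#' @param seed integer seed governing all draws of the assimilation run.
#' @return list of class `enkf_config`.
#' @export
enkf_config <- function(n_members = 50L, init_spread_frac = 0.1,
                        process_sd_abs = 0, process_sd_frac = 0.05,
                        obs_sd_abs = 0.05, obs_sd_frac = 0.1,
                        guard = TRUE, seed = 1L) {
  if (n_members < 2L) stop("need at least 2 ensemble members", call. = FALSE)
  structure(list(n_members = as.integer(n_members),
                 init_spread_frac = init_spread_frac,
                 process_sd_abs = process_sd_abs,
                 process_sd_frac = process_sd_frac,
                 obs_sd_abs = obs_sd_abs, obs_sd_frac = obs_sd_frac,
                 guard = isTRUE(guard), seed = as.integer(seed)),
            class = "enkf_config")
}

#' Run the EnKF over an assimilation window
#'
#' Generic day loop over any forecast operator: each day every member is
#' advanced by `model_step`, process noise is added to its LAI, and on days
#' with an observation the perturbed-observation EnKF update is applied —
#' observation ensemble `D_t = obs + noise`, covariances with divisor
#' `N - 1`, gain `K = A_c (A_c + D_c)^{-1}` (H = identity on LAI), the
#' divergence guard of [expansion_parameter()], and the member-wise analysis
#' equation. After inflation the effective gain is clipped at 1 so the
#' analysis cannot overshoot past the observation.
#'
#' @param members list of member states (any type `model_step` accepts), or
#'   a numeric vector for a scalar toy system.
#' @param n_days number of days in the window.
#' @param model_step function `(state, day_index) -> state`; the one-day
#'   forecast operator M.
#' @param obs data frame with columns `day` (index in 1..n_days) and `lai`;
#'   an update is performed on each listed day.
#' @param config an [enkf_config()].
#' @param state_lai,state_set_lai accessors mapping a member state to its
#'   LAI and writing a corrected LAI back (defaults handle `crop_state`
#'   objects via [rescale_lai()] and plain numerics).
#' @return list with
#'   \item{analysis_mean}{daily ensemble-mean LAI after any update}
#'   \item{forecast_mean}{daily ensemble-mean LAI before update}
#'   \item{gain_log}{data frame: day, k, sigma1_sq, sigma2_sq, e, applied,
#'     r_draw}
#'   \item{members}{final member states}
#'   \item{member_lai}{matrix (n_days x N) of member LAI after update}
#' @export
assimilate_window <- function(members, n_days, model_step, obs, config,
                              state_lai = default_state_lai,
                              state_set_lai = default_state_set_lai) {
  if (is.numeric(members)) members <- as.list(members)
  n <- length(members)
  if (n < 2L) stop("need at least 2 ensemble members", call. = FALSE)
  if (is.null(obs) || nrow(obs) == 0L) {
    warning("no observations in window; returning pure forecast")
    obs <- data.frame(day = integer(0), lai = numeric(0))
  } else if (any(obs$day < 1 | obs$day > n_days)) {
    stop("observation days must lie within the window", call. = FALSE)
  }
  set.seed(config$seed)
  analysis_mean <- forecast_mean <- rep(NA_real_, n_days)
  member_lai <- matrix(NA_real_, n_days, n)
  logs <- vector("list", n_days)
  obs_series <- rep(NA_real_, n_days)
  obs_series[obs$day] <- obs$lai

  for (t in seq_len(n_days)) {
    for (i in seq_len(n)) {
      members[[i]] <- model_step(members[[i]], t)
      lai <- state_lai(members[[i]])
      sd_i <- config$process_sd_abs + config$process_sd_frac * lai
      if (sd_i > 0) {
        lai <- max(0, lai + stats::rnorm(1, 0, sd_i))
        members[[i]] <- state_set_lai(members[[i]], lai)
      }
    }
    lais <- vapply(members, state_lai, numeric(1))
    forecast_mean[t] <- mean(lais)

    if (!is.na(obs_series[t])) {
      y <- obs_series[t]
      obs_sd <- config$obs_sd_abs + config$obs_sd_frac * y
      d_t <- pmax(0, y + stats::rnorm(n, 0, obs_sd))
      a_c <- stats::var(lais)
      d_c <- stats::var(d_t)
      k <- if (a_c + d_c > 0) a_c / (a_c + d_c) else 0
      r_draw <- stats::runif(1)
      s1 <- s2 <- NA_real_; e <- NA_real_; applied <- FALSE
      if (config$guard && t >= 2) {
        upto <- seq_len(t)
        s1 <- stats::var(obs_series[upto], na.rm = TRUE)
        s2 <- stats::var(forecast_mean[upto])
        if (is.finite(s1) && is.finite(s2) && s2 > 0) {
          guard_res <- expansion_parameter(r_draw, n_days, t, s1, s2)
          e <- guard_res$e; applied <- guard_res$applied
          if (applied) k <- min(k * e, 1)
        }
      }
      lais <- analysis_update(lais, d_t, k)
      for (i in seq_len(n))
        members[[i]] <- state_set_lai(members[[i]], lais[i])
      logs[[t]] <- data.frame(day = t, k = k, sigma1_sq = s1, sigma2_sq = s2,
                              e = e, applied = applied, r_draw = r_draw)
    }
    analysis_mean[t] <- mean(lais)
    member_lai[t, ] <- lais
  }
  list(analysis_mean = analysis_mean, forecast_mean = forecast_mean,
       gain_log = do.call(rbind, logs), members = members,
       member_lai = member_lai)
}

#' @rdname assimilate_window
#' @param state a member state.
#' @export
default_state_lai <- function(state) {
  if (inherits(state, "crop_state")) state$lai_green else as.numeric(state)
}

#' @rdname assimilate_window
#' @param lai corrected LAI to write back.
#' @export
default_state_set_lai <- function(state, lai) {
  if (inherits(state, "crop_state")) rescale_lai(state, lai) else lai
}

#' Assimilate RS-based LAI into the crop model over a season window
#'
#' Builds an initial crop-state ensemble by multiplicative lognormal
#' perturbation of the initial LAI, then runs [assimilate_window()] with the
#' daily crop model as forecast operator. Each member carries its own soil
#' moisture; the stress factors are recomputed per member per day.
#'
#' @param params a [crop_params()] object.
#' @param weather season weather covering the window (one row per day).
#' @param san soil available nutrients (plot level or one quadrat).
#' @param obs data frame with columns `doy`, `lai` — the (daily,
#'   IDW-interpolated) RS-based LAI.
#' @param config an [enkf_config()].
#' @param init optional initial `crop_state`.
#' @return as [assimilate_window()], plus `doy` (the weather days).
#' @export
assimilate_season <- function(params, weather, san, obs,
                              config = enkf_config(), init = NULL) {
  n_days <- nrow(weather)
  base <- if (is.null(init)) init_crop_state(params, weather$doy[1L]) else init
  set.seed(sub_seed(config$seed, 1L))
  members <- lapply(seq_len(config$n_members), function(i) {
    rescale_lai(base, base$lai_green *
                  stats::rlnorm(1, 0, config$init_spread_frac))
  })
  wl <- weather_rows(weather)
  step <- function(state, t) {
    stress <- stress_factors(state$sm, san, params)
    advance_day(state, wl[[t]], stress, params)
  }
  obs_idx <- data.frame(day = match(obs$doy, weather$doy), lai = obs$lai)
  if (anyNA(obs_idx$day))
    stop("observation doys must match weather days", call. = FALSE)
  res <- assimilate_window(members, n_days, step, obs_idx, config)
  res$doy <- weather$doy
  res
}
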