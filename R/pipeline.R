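#' Delimit the three growth stages from the field-campaign dates
#'
#' The early/mid boundary is the floor of the midpoint of the first two
#' campaigns and the mid/late boundary the floor of the midpoint of the last
#' two, so with campaigns on 29 June, 30 July and 25 August (DOY 180, 211,
#' 237 in a non-leap year) the early stage runs to 14 July (DOY 195) and the
#' late stage starts on 12 August (DOY 224). `early_end_doy` is the last
#' early-stage day and `late_start_doy` the first late-stage day, both
#' inclusive.
#'
#' @param campaign_doys at least three sorted campaign days of year.
#' @return list with `early_end_doy` and `late_start_doy`.
#' @export
delimit_stages <- function(campaign_doys) {
  if (length(campaign_doys) < 3L)
    stop("need at least 3 campaign dates", call. = FALSE)
  if (is.unsorted(campaign_doys, strictly = TRUE))
    stop("campaign dates must be strictly increasing", call. = FALSE)
  k <- length(campaign_doys)
  list(early_end_doy = floor((campaign_doys[1L] + campaign_doys[2L]) / 2),
       late_start_doy = floor((campaign_doys[k - 1L] + campaign_doys[k]) / 2))
}

#' Inverse-distance-weighted interpolation of dated LAI to a daily series
#'
#' `value(t) = sum(w_i * lai_i) / sum(w_i)` with `w_i = |t - doy_i|^-power`;
#' a target day coinciding with an observation returns that observation
#' exactly.
#'
#' @param obs_doys observation days of year.
#' @param obs_lai observed LAI values, same length.
#' @param target_doys days to interpolate to.
#' @param power IDW power (> 0, default 2).
#' @return numeric vector of interpolated LAI, one per target day.
#' @export
idw_daily <- function(obs_doys, obs_lai, target_doys, power = 2) {
  if (length(obs_doys) == 0L) stop("no observations to interpolate",
                                   call. = FALSE)
  if (length(obs_doys) != length(obs_lai))
    stop("`obs_doys` and `obs_lai` must have equal length", call. = FALSE)
  if (power <= 0) stop("`power` must be > 0", call. = FALSE)
  vapply(target_doys, function(t) {
    d <- abs(t - obs_doys)
    hit <- d == 0
    if (any(hit)) return(mean(obs_lai[hit]))
    w <- d^(-power)
    sum(w * obs_lai) / sum(w)
  }, numeric(1))
}

#' Hybrid method: assimilate until tasseling, then free-run the crop model
#'
#' Runs the EnKF from the start of the window until the switch — by default
#' the first day on which the analysis-mean development stage reaches
#' DVS = 1 (the beginning of tasseling), alternatively a fixed day of year —
#' then collapses the ensemble to its analysis-mean state and lets the
#' deterministic crop model run to the end of the season with no further
#' updates. This avoids the late-season corruption of RS-based LAI by
#' reflectance saturation and senescing leaves, while keeping the benefit of
#' assimilation up to tasseling.
#'
#' @inheritParams assimilate_season
#' @param switch_rule `"dvs>=1"` (default) or a numeric day of year.
#' @return list with `doy`, `lai` (daily plot LAI), `switch_doy`,
#'   `gain_log`, `switch_state`.
#' @export
run_hybrid <- function(params, weather, san, obs, config = enkf_config(),
                       switch_rule = "dvs>=1", init = NULL) {
  n_days <- nrow(weather)
  if (is.null(obs) || nrow(obs) == 0L) {
    sim <- simulate_season(params, weather, san, init = init)
    warning("no observations: hybrid reduces to the free-running crop model")
    return(list(doy = weather$doy, lai = sim$trajectory$lai_green,
                switch_doy = NA_integer_, gain_log = NULL,
                switch_state = NULL))
  }
  # phenology is weather-driven and identical across members, so the DVS=1
  # switch day is deterministic and known before running the ensemble
  teff <- pmax(0, (weather$tmax + weather$tmin) / 2 - params$tbase)
  dvs_daily <- dvs_update(cumsum(teff), params)
  switch_idx <- if (identical(switch_rule, "dvs>=1")) {
    which(dvs_daily >= 1)[1L]
  } else {
    match(switch_rule, weather$doy)
  }
  if (is.na(switch_idx)) {
    warning("switch never reached; returning full-season assimilation")
    res <- assimilate_season(params, weather, san, obs, config, init = init)
    return(list(doy = weather$doy, lai = res$analysis_mean,
                switch_doy = NA_integer_, gain_log = res$gain_log,
                switch_state = NULL))
  }
  # assimilate only up to the switch, then free-run from the collapsed
  # (ensemble-mean) state
  res_sw <- assimilate_season(params, weather[seq_len(switch_idx), ], san,
                              obs[obs$doy <= weather$doy[switch_idx], ,
                                  drop = FALSE],
                              config, init = init)
  mean_state <- collapse_ensemble(res_sw$members)
  lai <- res_sw$analysis_mean
  if (switch_idx < n_days) {
    free <- simulate_season(params,
                            weather[(switch_idx + 1L):n_days, , drop = FALSE],
                            san, init = mean_state)
    lai <- c(lai, free$trajectory$lai_green)
  }
  list(doy = weather$doy, lai = lai, switch_doy = weather$doy[switch_idx],
       gain_log = res_sw$gain_log, switch_state = mean_state)
}

#' Collapse a crop-state ensemble to its mean state
#'
#' All members share the weather-driven phenology and cohort age structure
#' (updates only rescale cohort areas), so the mean state is the first
#' member rescaled to the ensemble-mean LAI, with the biomass pools and soil
#' moisture averaged.
#'
#' @param members list of `crop_state` members.
#' @return a single `crop_state`.
#' @export
collapse_ensemble <- function(members) {
  lais <- vapply(members, function(s) s$lai_green, numeric(1))
  state <- rescale_lai(members[[1L]], mean(lais))
  for (f in c("w_stem", "w_storage", "w_root", "sm"))
    state[[f]] <- mean(vapply(members, function(s) s[[f]], numeric(1)))
  state$w_leaf <- mean(vapply(members, function(s) s$w_leaf, numeric(1)))
  state
}

#' Daily RS-based LAI from per-date VI models
#'
#' Fits one linear LAI-on-VI model per field-campaign date (selecting the
#' best index per date by |r|), applies to each flight date's reflectance
#' the model fitted on the nearest campaign date, and interpolates those
#' per-flight plot-mean predictions to a daily series with [idw_daily()]
#' (LAI is interpolated, not model coefficients).
#'
#' @param reflectance per-quadrat, per-flight-date reflectance table
#'   (columns `quadrat_id`, `doy`, five bands).
#' @param field_obs per-quadrat field LAI (columns `quadrat_id`, `doy`,
#'   `lai`); dates present here with >= 3 matched quadrats become model
#'   dates.
#' @param target_doys days to interpolate to.
#' @param power IDW power.
#' @return list with `daily` (data frame `doy`, `lai`), `models` (one
#'   `lai_vi_model` per campaign date), `per_date` (data frame `doy`, `lai`
#'   of plot-mean predictions per flight date) and `per_quadrat` (data frame
#'   `quadrat_id`, `doy`, `lai`).
#' @export
vi_daily_lai <- function(reflectance, field_obs, target_doys, power = 2) {
  model_doys <- sort(unique(field_obs$doy))
  models <- list()
  for (d in as.character(model_doys)) {
    dd <- as.numeric(d)
    refl_d <- reflectance[reflectance$doy == dd, , drop = FALSE]
    obs_d <- field_obs[field_obs$doy == dd, , drop = FALSE]
    m <- merge(refl_d, obs_d[, c("quadrat_id", "lai")], by = "quadrat_id")
    if (nrow(m) < 3L) next
    fits <- lapply(vi_names(), function(ix)
      fit_linear_model(compute_vi(m, ix), m$lai, ix))
    names(fits) <- vi_names()
    models[[d]] <- fits[[select_best_vi(fits)]]
  }
  if (length(models) == 0L)
    stop("no campaign date has >= 3 matched quadrats", call. = FALSE)
  fitted_doys <- as.numeric(names(models))

  flight_doys <- sort(unique(reflectance$doy))
  preds <- list(); per_q <- list()
  for (d in as.character(flight_doys)) {
    dd <- as.numeric(d)
    mod <- models[[which.min(abs(fitted_doys - dd))]]
    refl_d <- reflectance[reflectance$doy == dd, , drop = FALSE]
    lai_q <- estimate_lai_map(refl_d, mod)
    preds[[d]] <- data.frame(doy = dd, lai = mean(lai_q, na.rm = TRUE))
    per_q[[d]] <- data.frame(quadrat_id = refl_d$quadrat_id, doy = dd,
                             lai = as.numeric(lai_q))
  }
  per_date <- do.call(rbind, preds)
  daily <- data.frame(doy = target_doys,
                      lai = idw_daily(per_date$doy, per_date$lai,
                                      target_doys, power))
  list(daily = daily, models = models, per_date = per_date,
       per_quadrat = do.call(rbind, per_q))
}

#' Run the three-stage combined LAI estimation for a whole season
#'
#' Early stage (season start to `early_end_doy`, inclusive): plot-mean LAI
#' from the per-date VI empirical models, interpolated daily. Mid stage
#' (up to `late_start_doy - 1`): EnKF assimilation of the daily RS-based LAI
#' into the crop model, run from the season start. Late stage (from
#' `late_start_doy`): the hybrid method — the same assimilation halted at
#' the switch, then the free-running crop model. One seed governs every
#' stochastic component. Operates on the plot-mean trajectory.
#'
#' @param params a [crop_params()] object.
#' @param weather season weather.
#' @param san plot-level soil available nutrients (one row).
#' @param reflectance,field_obs campaign tables as in [vi_daily_lai()].
#' @param stages a [delimit_stages()] result (defaults to delimitation from
#'   the field-campaign dates).
#' @param config an [enkf_config()].
#' @return list of class `season_result`: data frame `season` (`doy`, `lai`,
#'   `method` in \{"vi", "assimilation", "hybrid"\}), `rs_daily` (the daily
#'   RS-based LAI), `vi_models`, `gain_log`, `switch_doy`, `seed`.
#' @export
run_combined <- function(params, weather, san, reflectance, field_obs,
                         stages = NULL, config = enkf_config()) {
  if (is.null(stages))
    stages <- delimit_stages(sort(unique(field_obs$doy)))
  doy <- weather$doy
  if (stages$early_end_doy < doy[1L] || stages$early_end_doy >=
      stages$late_start_doy)
    stop("stage boundaries must be ordered inside the season", call. = FALSE)

  vi <- vi_daily_lai(reflectance, field_obs, doy)
  early_days <- doy <= stages$early_end_doy
  if (!any(doy <= stages$early_end_doy & doy %in% vi$per_date$doy) &&
      min(vi$per_date$doy) > stages$early_end_doy)
    warning("no VI model date inside the early stage; using nearest date")

  assim <- assimilate_season(params, weather, san,
                             obs = vi$daily[, c("doy", "lai")], config)
  hybrid <- run_hybrid(params, weather, san,
                       obs = vi$daily[, c("doy", "lai")], config)

  lai <- numeric(length(doy)); method <- character(length(doy))
  lai[early_days] <- vi$daily$lai[early_days]
  method[early_days] <- "vi"
  mid_days <- !early_days & doy < stages$late_start_doy
  lai[mid_days] <- assim$analysis_mean[mid_days]
  method[mid_days] <- "assimilation"
  late_days <- doy >= stages$late_start_doy
  lai[late_days] <- hybrid$lai[late_days]
  method[late_days] <- "hybrid"

  structure(list(
    season = data.frame(doy = doy, lai = lai, method = method),
    rs_daily = vi$daily, vi_models = vi$models,
    vi_per_quadrat = vi$per_quadrat,
    gain_log = assim$gain_log, switch_doy = hybrid$switch_doy,
    assimilation = assim$analysis_mean, hybrid_lai = hybrid$lai,
    stages = stages, seed = config$seed), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  tab <- table(x$season$method)
  cat("Combined-season LAI estimate:",
      sprintf("%d days (%s)", nrow(x$season),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")),
      "\n")
  cat(sprintf("  stages: early to DOY %d, late from DOY %d; hybrid switch DOY %s\n",
              x$stages$early_end_doy, x$stages$late_start_doy,
              as.character(x$switch_doy)))
  invisible(x)
}
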