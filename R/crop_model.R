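#' Default crop and soil parameter set
#'
#' Returns the parameter list driving the reduced-order daily maize
#' simulator. Phenology, dry-matter partitioning, conversion efficiencies,
#' leaf life span and the soil-water constants follow the calibrated
#' spring-maize values (thermal time to anthesis `tsum1` = 890 degC d, to
#' maturity `tsum2` = 710 degC d, leaf span 28 days at 35 degC, field
#' capacity 0.46, wilting point 0.20, saturation 0.57 cm3/cm3, maximum
#' rooting depth 2.4 m). Partitioning fractions are piecewise-linear tables
#' against development stage (DVS); at every knot the above-ground fractions
#' `fltb + fstb + fotb` sum to 1.
#'
#' The remaining constants close the surrogate model and are documented
#' configuration, not field-calibrated values: base temperature 8 degC,
#' canopy extinction coefficient 0.6, specific leaf area 0.0022 ha/kg,
#' light-use efficiency `lue` (kg dry matter per ha per MJ m-2 d-1 of global
#' radiation at closed canopy), a daily evapotranspiration demand `et_demand`
#' (mm/d) and Michaelis-type nutrient half-saturations `h_n`, `h_p`, `h_k`
#' (mg/kg) chosen so that 100 mg/kg of each nutrient gives a factor of 0.9.
#'
#' @param ... named overrides of any default.
#' @return an object of class `crop_params` (a list).
#' @export
crop_params <- function(...) {
  p <- list(
    tsum1 = 890, tsum2 = 710,            # degC d
    tbase = 8,                           # degC
    cvl = 0.64, cvo = 0.81, cvr = 0.70, cvs = 0.66,  # kg/kg
    frtb = data.frame(dvs = c(0, 0.5, 1, 1.3, 2),
                      value = c(0.40, 0.25, 0.05, 0.00, 0.00)),
    fltb = data.frame(dvs = c(0, 0.5, 1, 1.3, 2),
                      value = c(0.62, 0.62, 0.18, 0.12, 0.05)),
    fstb = data.frame(dvs = c(0, 0.5, 1, 1.3, 2),
                      value = c(0.38, 0.38, 0.57, 0.19, 0.21)),
    fotb = data.frame(dvs = c(0, 0.5, 1, 1.3, 2),
                      value = c(0.00, 0.00, 0.25, 0.69, 0.74)),
    span = 28,                           # days at 35 degC
    smfcf = 0.46, smw = 0.20, sm0 = 0.57,  # cm3/cm3
    rdmcr = 2.4,                         # m
    h_n = 100 / 9, h_p = 100 / 9, h_k = 100 / 9,  # mg/kg half-saturations
    lue = 22,                            # kg ha-1 per MJ m-2 d-1
    sla = 0.0022,                        # ha/kg
    k_ext = 0.6,
    et_demand = 4,                       # mm/d at full supply
    lai_min_light = 0.01,                # seedling light-interception floor
    lai_init = 0.05, sm_init = 0.35
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  if (p$tsum1 <= 0 || p$tsum2 <= 0) stop("tsum1, tsum2 must be > 0",
                                         call. = FALSE)
  if (!(0 <= p$smw && p$smw < p$smfcf && p$smfcf < p$sm0 && p$sm0 <= 1))
    stop("need 0 <= smw < smfcf < sm0 <= 1", call. = FALSE)
  if (p$span <= 0) stop("span must be > 0", call. = FALSE)
  sums <- p$fltb$value + p$fstb$value + p$fotb$value
  if (any(abs(sums - 1) > 1e-9))
    stop("fltb + fstb + fotb must interpolate to 1 at every DVS knot",
         call. = FALSE)
  structure(p, class = "crop_params")
}

#' Initial crop state at emergence
#'
#' One live leaf cohort of physiological age 0 carries the initial LAI; the
#' leaf dry-weight pool is set consistently through the specific leaf area.
#'
#' @param params a [crop_params()] object.
#' @param doy emergence day of year.
#' @return an object of class `crop_state`.
#' @export
init_crop_state <- function(params, doy = 148L) {
  stopifnot(inherits(params, "crop_params"))
  structure(list(
    doy = doy, tt = 0, dvs = 0,
    lai_green = params$lai_init,
    lai_brown = 0,
    cohort_age = 0,                          # days at 35 degC
    cohort_lai = params$lai_init,
    w_leaf = params$lai_init / params$sla,   # kg/ha
    w_stem = 0, w_storage = 0, w_root = 0,
    sm = params$sm_init,
    assim_in = 0, pool_out = 0               # mass-balance accumulators
  ), class = "crop_state")
}

#' Development stage from accumulated thermal time
#'
#' `dvs = tt/tsum1` before anthesis, `1 + (tt - tsum1)/tsum2` after, clamped
#' at 2 (maturity). DVS 0 is emergence, 1 the beginning of tasseling.
#'
#' @param tt accumulated effective temperature (degC d), >= 0.
#' @param params a [crop_params()] object.
#' @return development stage in \[0, 2\].
#' @export
dvs_update <- function(tt, params) {
  if (any(tt < 0)) stop("`tt` must be >= 0", call. = FALSE)
  ifelse(tt <= params$tsum1, tt / params$tsum1,
         pmin(2, 1 + (tt - params$tsum1) / params$tsum2))
}

#' Water and nutrient stress factors
#'
#' Water: fraction of plant-available water,
#' `clamp((sm - smw)/(smfcf - smw), 0, 1)`. Nutrients: Liebig minimum over
#' N, P, K of the saturating response `x/(x + h_x)` with half-saturation
#' constants from `params` — a deliberately simple stand-in for a full
#' soil-nutrient submodel, driven directly by measured soil available
#' nutrient (SAN) content.
#'
#' @param sm soil moisture (cm3/cm3).
#' @param san list or one-row data frame with `n_avail`, `p_avail`, `k_avail`
#'   (mg/kg).
#' @param params a [crop_params()] object.
#' @return list with `f_water` and `f_nutrient`, both in \[0, 1\].
#' @export
stress_factors <- function(sm, san, params) {
  if (params$smfcf <= params$smw)
    stop("configuration error: smfcf must exceed smw", call. = FALSE)
  f_water <- clamp((sm - params$smw) / (params$smfcf - params$smw), 0, 1)
  f_nutrient <- min(san$n_avail / (san$n_avail + params$h_n),
                    san$p_avail / (san$p_avail + params$h_p),
                    san$k_avail / (san$k_avail + params$h_k))
  list(f_water = f_water, f_nutrient = clamp(f_nutrient, 0, 1))
}

#' Advance the crop state by one day
#'
#' Daily order of operations:
#' \enumerate{
#'   \item thermal time `tt += max(0, (tmax+tmin)/2 - tbase)`; DVS via
#'     [dvs_update()]; growth stops once DVS = 2 (cohorts keep aging);
#'   \item gross growth `G = lue * radiation * (1 - exp(-k_ext * LAI)) *
#'     f_water * f_nutrient` (kg/ha), with LAI floored at `lai_min_light`
#'     in the interception term so a zeroed canopy can re-establish;
#'   \item the root share `frtb(dvs) * G` is converted by `cvr`; the
#'     above-ground remainder is split by `fltb/fstb/fotb(dvs)` and converted
#'     by `cvl/cvs/cvo`;
#'   \item a new leaf cohort adds `sla * dW_leaf` of green LAI;
#'   \item every cohort ages by `Teff/(35 - tbase)` days (leaf life span is
#'     counted at a 35 degC reference); cohorts older than `span` die and
#'     their area moves from green to brown LAI;
#'   \item soil-water bucket: `sm += (precip - ET)/(1000 * rdmcr)`, clipped
#'     to \[0, sm0\], with `ET = et_demand * f_water`.
#' }
#'
#' @param state a `crop_state`.
#' @param weather one weather day: list with `doy`, `tmin`, `tmax`,
#'   `radiation`, `precip`.
#' @param stress list with `f_water`, `f_nutrient` (from [stress_factors()]).
#' @param params a [crop_params()] object.
#' @return the updated `crop_state`.
#' @export
advance_day <- function(state, weather, stress, params) {
  teff <- max(0, (weather$tmax + weather$tmin) / 2 - params$tbase)
  state$tt <- state$tt + teff
  state$dvs <- dvs_update(state$tt, params)
  state$doy <- weather$doy

  if (state$dvs < 2) {
    # seedlings intercept at least a floor of light, so growth can restart
    # from a zeroed canopy (stand-in for temperature-driven juvenile growth)
    lai_light <- max(state$lai_green, params$lai_min_light)
    g <- params$lue * weather$radiation *
      (1 - exp(-params$k_ext * lai_light)) *
      stress$f_water * stress$f_nutrient
  } else {
    g <- 0
  }
  fr <- interp_table(params$frtb, state$dvs)
  fl <- interp_table(params$fltb, state$dvs)
  fs <- interp_table(params$fstb, state$dvs)
  fo <- interp_table(params$fotb, state$dvs)
  d_root    <- g * fr * params$cvr
  g_above   <- g * (1 - fr)
  d_leaf    <- g_above * fl * params$cvl
  d_stem    <- g_above * fs * params$cvs
  d_storage <- g_above * fo * params$cvo
  state$w_root    <- state$w_root + d_root
  state$w_leaf    <- state$w_leaf + d_leaf
  state$w_stem    <- state$w_stem + d_stem
  state$w_storage <- state$w_storage + d_storage
  state$assim_in  <- state$assim_in + g
  state$pool_out  <- state$pool_out + d_root + d_leaf + d_stem + d_storage

  # cohort aging in days-at-35-degC, then recruitment of today's growth
  state$cohort_age <- state$cohort_age + teff / (35 - params$tbase)
  dead <- state$cohort_age > params$span
  if (any(dead)) {
    state$lai_brown <- state$lai_brown + sum(state$cohort_lai[dead])
    state$cohort_age <- state$cohort_age[!dead]
    state$cohort_lai <- state$cohort_lai[!dead]
  }
  if (d_leaf > 0) {
    state$cohort_age <- c(state$cohort_age, 0)
    state$cohort_lai <- c(state$cohort_lai, params$sla * d_leaf)
  }
  state$lai_green <- sum(state$cohort_lai)

  et <- params$et_demand * stress$f_water
  state$sm <- clamp(state$sm + (weather$precip - et) / (1000 * params$rdmcr),
                    0, params$sm0)
  state
}

#' Simulate a whole season of daily crop growth
#'
#' Deterministic day loop of [advance_day()] with stress factors recomputed
#' from the current soil moisture and the quadrat's soil available nutrients
#' each morning. The trajectory has one row per weather day.
#'
#' @param params a [crop_params()] object.
#' @param weather data frame with columns `doy`, `tmin`, `tmax`, `radiation`,
#'   `precip` (one row per day; see [gen_weather()]).
#' @param san soil available nutrients for this quadrat (`n_avail`,
#'   `p_avail`, `k_avail` in mg/kg).
#' @param init optional initial `crop_state`; defaults to
#'   [init_crop_state()] at the first weather day.
#' @return list with `trajectory` (data frame: doy, dvs, lai_green,
#'   lai_brown, w_leaf, w_stem, w_storage, w_root, sm) and `final_state`.
#' @export
simulate_season <- function(params, weather, san, init = NULL) {
  if (NROW(weather) == 0L) stop("`weather` is empty", call. = FALSE)
  state <- if (is.null(init)) init_crop_state(params, weather$doy[1L]) else init
  n <- nrow(weather)
  out <- data.frame(doy = weather$doy, dvs = NA_real_, lai_green = NA_real_,
                    lai_brown = NA_real_, w_leaf = NA_real_,
                    w_stem = NA_real_, w_storage = NA_real_,
                    w_root = NA_real_, sm = NA_real_)
  wl <- weather_rows(weather)
  for (i in seq_len(n)) {
    stress <- stress_factors(state$sm, san, params)
    state <- advance_day(state, wl[[i]], stress, params)
    out$dvs[i] <- state$dvs
    out$lai_green[i] <- state$lai_green
    out$lai_brown[i] <- state$lai_brown
    out$w_leaf[i] <- state$w_leaf
    out$w_stem[i] <- state$w_stem
    out$w_storage[i] <- state$w_storage
    out$w_root[i] <- state$w_root
    out$sm[i] <- state$sm
  }
  list(trajectory = out, final_state = state)
}

#' Rescale the green LAI of a crop state
#'
#' Multiplies every live cohort's area contribution (ages unchanged) and the
#' leaf dry-weight pool by `new_lai / lai_green`, so an externally corrected
#' LAI (e.g., an EnKF analysis value) can be pushed back into the mechanistic
#' state. If the state carries no green leaf area and `new_lai > 0`, a single
#' fresh cohort of age 0 is created.
#'
#' @param state a `crop_state`.
#' @param new_lai target green LAI (m2/m2), >= 0.
#' @return the rescaled `crop_state`.
#' @export
rescale_lai <- function(state, new_lai) {
  if (!is.finite(new_lai) || new_lai < 0)
    stop("`new_lai` must be finite and >= 0", call. = FALSE)
  if (state$lai_green == 0) {
    if (new_lai > 0) {
      state$cohort_age <- 0
      state$cohort_lai <- new_lai
      state$lai_green <- new_lai
    }
    return(state)
  }
  f <- new_lai / state$lai_green
  if (f == 0) {
    state$cohort_age <- numeric(0)
    state$cohort_lai <- numeric(0)
  } else {
    state$cohort_lai <- state$cohort_lai * f
  }
  state$w_leaf <- state$w_leaf * f
  state$lai_green <- sum(state$cohort_lai)
  state
}
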