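#' Generate a synthetic daily weather season
#'
#' Sinusoidal seasonal mean temperature with bounded daily noise, a fixed
#' diurnal range, seasonal global radiation and intermittent rainfall,
#' emulating a temperate-monsoon spring-maize season (emergence late May,
#' maturity by October). Fully reproducible for a fixed seed.
#'
#' The configured climate is: seasonal mean temperature
#' `t_mean + t_amp * cos(2*pi*(doy - t_peak_doy)/365)` (defaults 12 degC,
#' amplitude 10 degC, peak DOY 200), diurnal half-range 5 degC, radiation
#' `18 + 6 * cos(2*pi*(doy - 172)/365)` MJ m-2 d-1 plus noise, wet-day
#' probability 0.35 with exponential amounts (mean 8 mm).
#'
#' @param n_days number of days (>= 1).
#' @param start_doy first day of year.
#' @param seed integer seed.
#' @param t_mean,t_amp,t_peak_doy seasonal temperature configuration (degC,
#'   degC, day of year).
#' @return data frame with columns `doy`, `tmin`, `tmax`, `radiation`,
#'   `precip`; `tmax >= tmin`, `radiation >= 0`, `precip >= 0` on every day.
#' @export
gen_weather <- function(n_days, start_doy = 140L, seed = 1L,
                        t_mean = 12, t_amp = 10, t_peak_doy = 200) {
  if (!is.numeric(n_days) || n_days < 1) stop("`n_days` must be >= 1",
                                              call. = FALSE)
  n_days <- as.integer(n_days)
  doy <- start_doy + seq_len(n_days) - 1L
  set.seed(seed)
  tmean <- t_mean + t_amp * cos(2 * pi * (doy - t_peak_doy) / 365) +
    clamp(stats::rnorm(n_days, 0, 2), -5, 5)
  half_range <- pmax(0.5, 5 + stats::rnorm(n_days, 0, 1))
  radiation <- pmax(0.1, 18 + 6 * cos(2 * pi * (doy - 172) / 365) +
                      stats::rnorm(n_days, 0, 3))
  wet <- stats::runif(n_days) < 0.35
  precip <- ifelse(wet, stats::rexp(n_days, rate = 1 / 8), 0)
  data.frame(doy = doy, tmin = tmean - half_range, tmax = tmean + half_range,
             radiation = radiation, precip = precip)
}

#' Scene configuration for synthetic reflectance
#'
#' Per-band optical constants of the exponential-extinction soil/leaf mixing
#' model used by [synth_reflectance()]: bare-soil reflectance, green-leaf and
#' brown-leaf canopy asymptotes and an extinction coefficient per band, plus
#' noise levels. Defaults are generator configuration chosen to reproduce
#' the qualitative behaviours that degrade optical LAI retrieval late in the
#' season — index saturation at high LAI and brown leaves raising red and
#' depressing NIR reflectance — not measured values.
#'
#' @param rho_soil,rho_green,rho_brown named numeric vectors over
#'   `blue, green, red, rededge, nir`, each value in (0, 1).
#' @param k_b per-band extinction coefficients (> 0).
#' @param refl_noise_sd additive reflectance noise sd (unitless).
#' @param lai_obs_noise_sd field-LAI measurement noise sd (m2/m2).
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(
    rho_soil  = c(blue = 0.06, green = 0.10, red = 0.12, rededge = 0.18,
                  nir = 0.22),
    rho_green = c(blue = 0.03, green = 0.09, red = 0.05, rededge = 0.25,
                  nir = 0.45),
    rho_brown = c(blue = 0.10, green = 0.18, red = 0.22, rededge = 0.26,
                  nir = 0.25),
    k_b = c(blue = 0.6, green = 0.6, red = 0.65, rededge = 0.6, nir = 0.55),
    refl_noise_sd = 0.005, lai_obs_noise_sd = 0.2) {
  bands <- c("blue", "green", "red", "rededge", "nir")
  for (v in list(rho_soil, rho_green, rho_brown)) {
    if (!all(bands %in% names(v)) || any(v <= 0) || any(v >= 1))
      stop("reflectance asymptotes must be named over the five bands and lie in (0,1)",
           call. = FALSE)
  }
  if (any(k_b <= 0)) stop("extinction coefficients must be > 0", call. = FALSE)
  if (refl_noise_sd < 0 || lai_obs_noise_sd < 0)
    stop("noise sds must be >= 0", call. = FALSE)
  structure(list(rho_soil = rho_soil[bands], rho_green = rho_green[bands],
                 rho_brown = rho_brown[bands], k_b = k_b[bands],
                 refl_noise_sd = refl_noise_sd,
                 lai_obs_noise_sd = lai_obs_noise_sd),
            class = "scene_params")
}

#' Synthesize five-band canopy reflectance from green and brown LAI
#'
#' Beer-Lambert style soil/leaf mixing: for each band b,
#' `rho = rho_soil_b + (rho_mix_b - rho_soil_b) * (1 - exp(-k_b * LAI_tot))`
#' where `rho_mix_b` is the green/brown leaf asymptote mixture weighted by
#' the green and brown LAI fractions and `LAI_tot = lai_green + lai_brown`.
#' Optional Gaussian noise is added and the result clipped to (0, 1). The
#' exponential approach to the leaf asymptote reproduces the asymptotic
#' saturation of reflectance (and hence of vegetation indices) at high LAI.
#'
#' @param lai_green,lai_brown green and brown leaf area index (m2/m2, >= 0).
#' @param scene a [scene_params()] object.
#' @param noise if `FALSE`, the deterministic formula value is returned
#'   regardless of `scene$refl_noise_sd`.
#' @return list with `blue`, `green`, `red`, `rededge`, `nir`.
#' @export
synth_reflectance <- function(lai_green, lai_brown, scene, noise = TRUE) {
  if (lai_green < 0 || lai_brown < 0)
    stop("LAI values must be >= 0", call. = FALSE)
  tot <- lai_green + lai_brown
  if (tot > 0) {
    rho_mix <- (lai_green * scene$rho_green + lai_brown * scene$rho_brown) / tot
  } else {
    rho_mix <- scene$rho_soil
  }
  rho <- scene$rho_soil + (rho_mix - scene$rho_soil) *
    (1 - exp(-scene$k_b * tot))
  if (noise && scene$refl_noise_sd > 0)
    rho <- rho + stats::rnorm(length(rho), 0, scene$refl_noise_sd)
  rho <- clamp(rho, 1e-6, 1 - 1e-6)
  as.list(stats::setNames(rho, c("blue", "green", "red", "rededge", "nir")))
}

#' Generate per-quadrat soil available nutrients
#'
#' Uniform draws inside the spans observed for the study soils:
#' N 40-410, P 10-80, K 20-340 mg/kg.
#'
#' @param n_quadrats number of quadrats.
#' @param seed integer seed.
#' @return data frame `quadrat_id`, `n_avail`, `p_avail`, `k_avail`.
#' @export
gen_san <- function(n_quadrats, seed = 1L) {
  set.seed(seed)
  data.frame(quadrat_id = sprintf("Q%02d", seq_len(n_quadrats)),
             n_avail = stats::runif(n_quadrats, 40, 410),
             p_avail = stats::runif(n_quadrats, 10, 80),
             k_avail = stats::runif(n_quadrats, 20, 340))
}

#' Generate true LAI seasons, noisy field campaigns and synthetic reflectance
#'
#' Runs the crop simulator once per quadrat (its soil available nutrients set
#' the nutrient stress), then samples three field campaigns and synthesizes
#' five-band reflectance on the campaign dates. Field LAI observations are
#' the true green LAI plus additive Gaussian noise, truncated at 0. Brown
#' LAI (senesced cohorts, accumulating after DVS reaches 1) perturbs the
#' late-season reflectance. Every quadrat uses a stable sub-seed derived
#' from `seed`, so the output is reproducible and quadrats are independent.
#'
#' @param params a [crop_params()] object.
#' @param weather season weather (see [gen_weather()]).
#' @param san per-quadrat soil nutrients (see [gen_san()]).
#' @param campaign_doys field-campaign days of year (defaults to
#'   29 June / 30 July / 25 August of a non-leap year).
#' @param flight_doys UAV flight days of year on which reflectance is
#'   synthesized; must include the campaign dates. Defaults to six flights
#'   spanning emergence to late August.
#' @param scene a [scene_params()] object.
#' @param seed integer seed.
#' @return list with
#'   \item{truth}{data frame `quadrat_id`, `doy`, `lai_green`, `lai_brown`}
#'   \item{field_obs}{data frame `quadrat_id`, `doy`, `lai` (noisy, campaign
#'     dates only)}
#'   \item{reflectance}{data frame `quadrat_id`, `doy`, five band columns}
#' @export
gen_truth_and_obs <- function(params, weather, san,
                              campaign_doys = c(180L, 211L, 237L),
                              flight_doys = c(150L, 165L, 180L, 195L, 211L,
                                              237L),
                              scene = scene_params(), seed = 1L) {
  if (any(campaign_doys < min(weather$doy)) ||
      any(campaign_doys > max(weather$doy)))
    stop("campaign dates must lie within the weather span", call. = FALSE)
  flight_doys <- sort(unique(c(flight_doys, campaign_doys)))
  if (any(flight_doys < min(weather$doy)) ||
      any(flight_doys > max(weather$doy)))
    stop("flight dates must lie within the weather span", call. = FALSE)
  truth <- list(); obs <- list(); refl <- list()
  for (q in seq_len(nrow(san))) {
    sim <- simulate_season(params, weather, san[q, ])
    tr <- sim$trajectory
    qid <- san$quadrat_id[q]
    truth[[q]] <- data.frame(quadrat_id = qid, doy = tr$doy,
                             lai_green = tr$lai_green,
                             lai_brown = tr$lai_brown)
    set.seed(sub_seed(seed, q))
    idx <- match(campaign_doys, tr$doy)
    lai_noisy <- pmax(0, tr$lai_green[idx] +
                        stats::rnorm(length(idx), 0, scene$lai_obs_noise_sd))
    obs[[q]] <- data.frame(quadrat_id = qid, doy = campaign_doys,
                           lai = lai_noisy)
    fidx <- match(flight_doys, tr$doy)
    bands <- lapply(fidx, function(i)
      synth_reflectance(tr$lai_green[i], tr$lai_brown[i], scene))
    refl[[q]] <- data.frame(quadrat_id = qid, doy = flight_doys,
                            blue = vapply(bands, `[[`, 0, "blue"),
                            green = vapply(bands, `[[`, 0, "green"),
                            red = vapply(bands, `[[`, 0, "red"),
                            rededge = vapply(bands, `[[`, 0, "rededge"),
                            nir = vapply(bands, `[[`, 0, "nir"))
  }
  list(truth = do.call(rbind, truth),
       field_obs = do.call(rbind, obs),
       reflectance = do.call(rbind, refl))
}

#' Write the synthetic scene to CSV files
#'
#' @param scene_data result of [gen_truth_and_obs()].
#' @param weather the weather data frame.
#' @param san the soil-nutrient data frame.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_scene_csv <- function(scene_data, weather, san, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("weather.csv", "san.csv", "field_obs.csv",
                                "reflectance.csv", "truth.csv"))
  utils::write.csv(weather, files[1], row.names = FALSE)
  utils::write.csv(san, files[2], row.names = FALSE)
  utils::write.csv(scene_data$field_obs, files[3], row.names = FALSE)
  utils::write.csv(scene_data$reflectance, files[4], row.names = FALSE)
  utils::write.csv(scene_data$truth, files[5], row.names = FALSE)
  invisible(files)
}
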