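#' Calibration specification
#'
#' Names the free crop parameters with their bounds, the campaign dates and
#' the observed plot-mean LAI on each date. The default free-parameter set
#' mirrors the parameters that field data cannot pin down directly and are
#' instead optimized against LAI observations: `smfcf`, `smw`, `sm0`,
#' `rdmcr`, `span`.
#'
#' @param free named list of `c(lower, upper)` bounds, one entry per free
#'   crop parameter.
#' @param campaign_doys days of year with an observed LAI.
#' @param observed_lai plot-mean field LAI (m2/m2) per campaign date.
#' @return list of class `calibration_spec`.
#' @export
calibration_spec <- function(free, campaign_doys, observed_lai) {
  if (length(free) < 1L) stop("need at least one free parameter",
                              call. = FALSE)
  if (is.null(names(free)) || any(!nzchar(names(free))))
    stop("`free` must be a named list of bounds", call. = FALSE)
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop(sprintf("bounds for `%s` must be finite with lower < upper", nm),
           call. = FALSE)
  }
  if (length(campaign_doys) < 1L) stop("need at least one campaign date",
                                       call. = FALSE)
  if (length(campaign_doys) != length(observed_lai))
    stop("one observed LAI per campaign date required", call. = FALSE)
  structure(list(free = free, campaign_doys = campaign_doys,
                 observed_lai = observed_lai),
            class = "calibration_spec")
}

# squared LAI error of a candidate parameter vector on one campaign date
calib_objective <- function(theta, spec, params0, weather, san, date_index) {
  p <- params0
  for (j in seq_along(theta)) p[[names(spec$free)[j]]] <- theta[j]
  p <- tryCatch(do.call(crop_params, unclass(p)),
                error = function(e) NULL)
  if (is.null(p)) return(1e12)
  traj <- simulate_season(p, weather, san)$trajectory
  i <- match(spec$campaign_doys[date_index], traj$doy)
  if (is.na(i)) stop("campaign date outside the weather span", call. = FALSE)
  (traj$lai_green[i] - spec$observed_lai[date_index])^2
}

#' Calibrate the free parameters against one campaign date
#'
#' Minimizes the squared error between the simulated green LAI on the
#' campaign date and the observed plot-mean LAI, over the free parameters
#' within their bounds. One free parameter uses Brent's bounded
#' derivative-free search; several use a Nelder-Mead search with values
#' clamped to the bounds and one restart from the incumbent, with a fixed
#' budget of about 200 objective evaluations. If the target is unreachable
#' within the bounds the best bound endpoint is returned with
#' `bound_active = TRUE`.
#'
#' @param spec a [calibration_spec()].
#' @param date_index which campaign date (1-based).
#' @param params0 starting [crop_params()]; fixed parameters pass through.
#' @param weather,san as in [simulate_season()].
#' @return list with `theta` (named optimum), `objective`, `bound_active`,
#'   `warning_flag`.
#' @export
calibrate_once <- function(spec, date_index, params0, weather, san) {
  stopifnot(inherits(spec, "calibration_spec"))
  nms <- names(spec$free)
  lower <- vapply(spec$free, `[`, 0, 1L)
  upper <- vapply(spec$free, `[`, 0, 2L)
  f <- function(theta) calib_objective(theta, spec, params0, weather, san,
                                       date_index)
  if (length(nms) == 1L) {
    opt <- stats::optimize(f, lower = lower, upper = upper,
                           tol = (upper - lower) * 1e-6)
    theta <- opt$minimum; obj <- opt$objective
    # Brent never evaluates the endpoints; take one if it does better
    for (b in c(lower, upper)) {
      fb <- f(b)
      if (fb < obj) { theta <- b; obj <- fb }
    }
  } else {
    fc <- function(theta) f(clamp(theta, lower, upper))
    theta0 <- (lower + upper) / 2
    o1 <- stats::optim(theta0, fc, method = "Nelder-Mead",
                       control = list(maxit = 100))
    o2 <- stats::optim(clamp(o1$par, lower, upper), fc,
                       method = "Nelder-Mead", control = list(maxit = 100))
    best <- if (o2$value <= o1$value) o2 else o1
    theta <- clamp(best$par, lower, upper); obj <- best$value
  }
  names(theta) <- nms
  tol_bound <- (upper - lower) * 1e-6
  list(theta = theta, objective = obj,
       bound_active = any(theta <= lower + tol_bound |
                            theta >= upper - tol_bound),
       warning_flag = FALSE)
}

#' Calibrate once per campaign date and average the per-date optima
#'
#' The optimization is run independently for each campaign date; the final
#' value of each free parameter is the arithmetic mean of the per-date
#' optima. Fixed parameters pass through unchanged.
#'
#' @inheritParams calibrate_once
#' @return list with `params` (a [crop_params()] carrying the averaged
#'   values), `per_date` (matrix of per-date optima, dates in rows) and
#'   `objectives`.
#' @export
calibrate_mean <- function(spec, params0, weather, san) {
  stopifnot(inherits(spec, "calibration_spec"))
  n_dates <- length(spec$campaign_doys)
  per_date <- matrix(NA_real_, n_dates, length(spec$free),
                     dimnames = list(NULL, names(spec$free)))
  objs <- numeric(n_dates)
  for (d in seq_len(n_dates)) {
    res <- tryCatch(calibrate_once(spec, d, params0, weather, san),
                    error = function(e) e)
    if (inherits(res, "error"))
      stop(sprintf("calibration failed on date %d (completed %d): %s",
                   d, d - 1L, conditionMessage(res)), call. = FALSE)
    per_date[d, ] <- res$theta
    objs[d] <- res$objective
  }
  means <- colMeans(per_date)
  p <- unclass(params0)
  for (nm in names(means)) p[[nm]] <- unname(means[nm])
  list(params = do.call(crop_params, p), per_date = per_date,
       objectives = objs)
}
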