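#' Accuracy statistics of LAI estimates against field observations
#'
#' Fits the line `L_f = a * L + b` by least squares with the estimate `L` as
#' independent and the observation `L_obs` as dependent variable, then
#' reports
#' \itemize{
#'   \item `r`: Pearson correlation of `L` and `L_obs`;
#'   \item `r2`: `sum((L_f - L_mean)^2) / sum((L_obs - L_mean)^2)` with
#'     `L_mean` the mean of the observations — the fitted-line coefficient
#'     of determination (for this least-squares fit it equals `r^2`);
#'   \item `rmse`: `sqrt(mean((L - L_obs)^2))` — note this uses the raw
#'     estimates, not the fitted values, so an estimate offset by a constant
#'     keeps `r2 = 1` but pays the offset in RMSE;
#'   \item the significance class of `r` (see [significance_class()]).
#' }
#'
#' @param estimates numeric vector `L` of LAI estimates.
#' @param observed numeric vector `L_obs` of field LAI, same length (>= 3).
#' @return list of class `eval_result`: `r`, `r2`, `rmse`, `n`,
#'   `significance`, `a`, `b`.
#' @export
evaluate <- function(estimates, observed) {
  if (length(estimates) != length(observed))
    stop("`estimates` and `observed` must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(observed) == 0)
    stop("degenerate: `observed` is constant", call. = FALSE)
  if (stats::sd(estimates) == 0)
    stop("degenerate: `estimates` is constant", call. = FALSE)
  fit <- stats::lm(observed ~ estimates)
  a <- unname(stats::coef(fit)[2L]); b <- unname(stats::coef(fit)[1L])
  l_f <- a * estimates + b
  l_mean <- mean(observed)
  r <- stats::cor(estimates, observed)
  structure(list(
    r = r,
    r2 = sum((l_f - l_mean)^2) / sum((observed - l_mean)^2),
    rmse = sqrt(mean((estimates - observed)^2)),
    n = n,
    significance = significance_class(r, n),
    a = a, b = b), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("R = %.3f%s, R2 = %.3f, RMSE = %.3f (n = %d)\n", x$r,
              if (x$significance == "ns") "" else x$significance,
              x$r2, x$rmse, x$n))
  invisible(x)
}

#' Coefficient of variation in percent
#'
#' `CV = SD / Mean * 100` with the sample standard deviation (divisor
#' n - 1). Used as a saturation/heterogeneity diagnostic: a vegetation
#' index whose CV across quadrats falls toward the late season is losing
#' sensitivity to the underlying LAI variation.
#'
#' @param values numeric vector (>= 2 values, nonzero mean).
#' @return list with `cv` (percent), `sd`, `mean`.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is 0", call. = FALSE)
  s <- stats::sd(values)
  list(cv = s / m * 100, sd = s, mean = m)
}

#' Per-stage, per-campaign accuracy table
#'
#' Evaluates per-quadrat estimates of one or more methods against the field
#' campaigns: one [evaluate()] row per (method, campaign date) with at least
#' 3 matched quadrats, plus one pooled row per method over all campaigns.
#'
#' @param estimates data frame with columns `method`, `quadrat_id`, `doy`,
#'   `lai`.
#' @param field_obs data frame with columns `quadrat_id`, `doy`, `lai`.
#' @return data frame with columns `method`, `doy` (NA for pooled), `n`,
#'   `r`, `r2`, `rmse`, `significance`.
#' @export
stagewise_report <- function(estimates, field_obs) {
  rows <- list()
  for (meth in unique(estimates$method)) {
    est_m <- estimates[estimates$method == meth, , drop = FALSE]
    pooled_e <- numeric(0); pooled_o <- numeric(0)
    for (d in sort(unique(est_m$doy))) {
      e_d <- est_m[est_m$doy == d, , drop = FALSE]
      o_d <- field_obs[field_obs$doy == d, , drop = FALSE]
      m <- merge(e_d[, c("quadrat_id", "lai")],
                 o_d[, c("quadrat_id", "lai")],
                 by = "quadrat_id", suffixes = c("_est", "_obs"))
      if (nrow(m) < 3L) {
        warning(sprintf("campaign DOY %s for method %s: fewer than 3 matched quadrats, skipped",
                        d, meth))
        next
      }
      ev <- evaluate(m$lai_est, m$lai_obs)
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, doy = d, n = ev$n, r = ev$r, r2 = ev$r2,
                   rmse = ev$rmse, significance = ev$significance)
      pooled_e <- c(pooled_e, m$lai_est); pooled_o <- c(pooled_o, m$lai_obs)
    }
    if (length(pooled_e) >= 3L) {
      ev <- evaluate(pooled_e, pooled_o)
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, doy = NA_real_, n = ev$n, r = ev$r,
                   r2 = ev$r2, rmse = ev$rmse, significance = ev$significance)
    }
  }
  do.call(rbind, rows)
}

#' Root-mean-square error of a daily trajectory against truth
#'
#' Convenience for full-season comparisons of method trajectories with the
#' synthetic truth.
#'
#' @param est,truth numeric vectors, same length.
#' @return RMSE.
#' @export
rmse <- function(est, truth) {
  if (length(est) != length(truth))
    stop("length mismatch", call. = FALSE)
  sqrt(mean((est - truth)^2))
}
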