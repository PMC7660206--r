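#' Vegetation indices from five-band surface reflectance
#'
#' Computes one of the five vegetation indices used for maize LAI estimation
#' from calibrated surface reflectance. Band arguments are unitless
#' reflectances in \[0, 1\] for the five camera bands centred at 490 nm
#' (blue), 550 nm (green), 680 nm (red), 720 nm (red edge) and 800 nm (NIR).
#'
#' The indices are
#' \describe{
#'   \item{NDVI}{\eqn{(NIR - RED)/(NIR + RED)}}
#'   \item{RVI}{\eqn{NIR/RED}}
#'   \item{OSAVI}{\eqn{1.16 (NIR - RED)/(NIR + RED + 0.16)}}
#'   \item{EVI2}{\eqn{2.5 (NIR - RED)/(NIR + 2.4 RED + 1)}}
#'   \item{MTVI2}{\eqn{1.5 [1.2(NIR - GREEN) - 2.5(RED - GREEN)] /
#'     \sqrt{(2 NIR + 1)^2 - (6 NIR - 5\sqrt{RED}) - 0.5}}}
#' }
#'
#' @param bands a list or data frame with numeric elements `blue`, `green`,
#'   `red`, `rededge`, `nir` (vectors allowed; recycled together).
#' @param index_name one of `"NDVI"`, `"RVI"`, `"OSAVI"`, `"EVI2"`, `"MTVI2"`.
#' @return numeric vector of index values.
#' @examples
#' compute_vi(list(blue = .04, green = .08, red = .06, rededge = .2, nir = .4),
#'            "NDVI")
#' @export
compute_vi <- function(bands, index_name = c("NDVI", "RVI", "OSAVI", "EVI2",
                                             "MTVI2")) {
  index_name <- match.arg(index_name)
  nir <- bands$nir; red <- bands$red; green <- bands$green
  if (is.null(nir) || is.null(red))
    stop("`bands` must contain `nir` and `red`", call. = FALSE)
  if (any(c(nir, red, green) < 0, na.rm = TRUE) ||
      any(c(nir, red, green) > 1, na.rm = TRUE))
    stop("band reflectances must lie in [0, 1]", call. = FALSE)
  switch(index_name,
    NDVI = {
      if (any(nir + red == 0)) stop("NDVI undefined: NIR + RED = 0",
                                    call. = FALSE)
      (nir - red) / (nir + red)
    },
    RVI = {
      if (any(red == 0)) stop("RVI undefined: RED = 0", call. = FALSE)
      nir / red
    },
    OSAVI = 1.16 * (nir - red) / (nir + red + 0.16),
    EVI2 = 2.5 * (nir - red) / (nir + 2.4 * red + 1),
    MTVI2 = {
      if (is.null(green)) stop("MTVI2 needs the green band", call. = FALSE)
      disc <- (2 * nir + 1)^2 - (6 * nir - 5 * sqrt(red)) - 0.5
      if (any(disc < 0)) stop("MTVI2 undefined: negative discriminant",
                              call. = FALSE)
      1.5 * (1.2 * (nir - green) - 2.5 * (red - green)) / sqrt(disc)
    })
}

#' Names of the supported vegetation indices, in definition order
#'
#' The order is also the tie-break order used by [select_best_vi()].
#' @return character vector of the five index names.
#' @export
vi_names <- function() c("NDVI", "RVI", "OSAVI", "EVI2", "MTVI2")

#' Fit a linear LAI-on-VI empirical model
#'
#' Ordinary least squares of observed LAI on a vegetation index,
#' `LAI = a * VI + b`, as used to build the per-date empirical estimators.
#' The Pearson correlation and its significance class (two-sided t test)
#' are attached.
#'
#' @param vi numeric vector of index values.
#' @param lai_obs numeric vector of field LAI (m2/m2), same length.
#' @param index_name optional index label stored in the result.
#' @return an object of class `lai_vi_model`: list with `index_name`,
#'   `a` (slope), `b` (intercept), `r`, `n`, `significance`.
#' @export
fit_linear_model <- function(vi, lai_obs, index_name = NA_character_) {
  if (length(vi) != length(lai_obs))
    stop("`vi` and `lai_obs` must have equal length", call. = FALSE)
  if (length(vi) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(vi) == 0)
    stop("degenerate fit: `vi` is constant", call. = FALSE)
  fit <- stats::lm(lai_obs ~ vi)
  r <- stats::cor(vi, lai_obs)
  structure(list(index_name = index_name,
                 a = unname(stats::coef(fit)[2L]),
                 b = unname(stats::coef(fit)[1L]),
                 r = r, n = length(vi),
                 significance = significance_class(r, length(vi))),
            class = "lai_vi_model")
}

#' @export
print.lai_vi_model <- function(x, ...) {
  cat(sprintf("LAI ~ %s linear model: LAI = %.4f * VI + %.4f  (r = %.3f%s, n = %d)\n",
              x$index_name, x$a, x$b, x$r,
              if (x$significance == "ns") " ns" else x$significance, x$n))
  invisible(x)
}

#' Select the best vegetation index by correlation magnitude
#'
#' Picks the fitted model with the largest absolute Pearson correlation with
#' field LAI; ties are broken by the index definition order
#' (NDVI, RVI, OSAVI, EVI2, MTVI2).
#'
#' @param models a named list of `lai_vi_model` objects (names are index
#'   names), or an unnamed list whose elements carry `index_name`.
#' @return the winning index name (character scalar).
#' @export
select_best_vi <- function(models) {
  if (length(models) == 0L) stop("no models supplied", call. = FALSE)
  nm <- names(models)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(models, function(m) m$index_name, character(1))
  ord <- match(nm, vi_names())
  if (anyNA(ord)) stop("unknown index name among models", call. = FALSE)
  r_abs <- abs(vapply(models, function(m) m$r, numeric(1)))
  nm[order(-r_abs, ord)][1L]
}

#' Significance class of a Pearson correlation
#'
#' Two-sided t test of the correlation: `t = r * sqrt((n-2)/(1-r^2))` against
#' a t distribution with `n - 2` degrees of freedom. Returns `"**"` for
#' p < 0.01 (highly significant), `"*"` for p < 0.05, `"ns"` otherwise.
#' `|r| = 1` returns `"**"` by convention.
#'
#' @param r Pearson correlation coefficient.
#' @param n sample size (>= 3).
#' @return one of `"**"`, `"*"`, `"ns"`.
#' @export
significance_class <- function(r, n) {
  stopifnot_scalar(r, "r"); stopifnot_scalar(n, "n")
  if (n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (abs(r) > 1) stop("|r| cannot exceed 1", call. = FALSE)
  if (abs(r) == 1) return("**")
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Apply a fitted VI model to a reflectance table
#'
#' Computes `LAI = a * VI + b` per row of a reflectance table. Negative
#' predictions are clamped to 0 (physical bound) and the clamp count is
#' attached as attribute `"n_clamped"`. Rows where the index is undefined
#' yield `NA`.
#'
#' @param reflectance data frame with columns `blue`, `green`, `red`,
#'   `rededge`, `nir` (additional columns such as `quadrat_id`, `doy` are
#'   ignored).
#' @param model a `lai_vi_model`.
#' @return numeric vector of LAI estimates with attribute `n_clamped`.
#' @export
estimate_lai_map <- function(reflectance, model) {
  stopifnot(inherits(model, "lai_vi_model"))
  vi <- rep(NA_real_, nrow(reflectance))
  for (i in seq_len(nrow(reflectance))) {
    vi[i] <- tryCatch(compute_vi(reflectance[i, , drop = FALSE],
                                 model$index_name),
                      error = function(e) NA_real_)
  }
  lai <- model$a * vi + model$b
  n_clamped <- sum(lai < 0, na.rm = TRUE)
  lai[!is.na(lai) & lai < 0] <- 0
  attr(lai, "n_clamped") <- n_clamped
  lai
}
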