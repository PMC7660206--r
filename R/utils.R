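# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# linear interpolation in a (knot, value) table; constant beyond the ends.
# hand-rolled for speed: this sits in the innermost daily loop
interp_table <- function(tab, x) {
  k <- tab$dvs; v <- tab$value
  n <- length(k)
  if (x <= k[1L]) return(v[1L])
  if (x >= k[n]) return(v[n])
  i <- findInterval(x, k)
  v[i] + (v[i + 1L] - v[i]) * (x - k[i]) / (k[i + 1L] - k[i])
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# one plain list per weather day; avoids repeated data.frame row subsetting
# in the daily loops
weather_rows <- function(weather) {
  lapply(seq_len(nrow(weather)), function(i)
    list(doy = weather$doy[i], tmin = weather$tmin[i],
         tmax = weather$tmax[i], radiation = weather$radiation[i],
         precip = weather$precip[i]))
}

# derive a reproducible child seed (kept below 2^31) from a parent seed
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}
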