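test_that("development stage follows the two-phase thermal-time rule", {
  p <- crop_params()
  expect_equal(dvs_update(0, p), 0)
  expect_equal(dvs_update(890, p), 1)
  expect_equal(dvs_update(890 + 710, p), 2)
  expect_equal(dvs_update(445, p), 0.5)
  expect_equal(dvs_update(890 + 355, p), 1.5)
  expect_equal(dvs_update(5000, p), 2)  # clamped at maturity
  expect_error(dvs_update(-1, p), ">= 0")
})

test_that("parameter constructor validates its invariants", {
  expect_error(crop_params(tsum1 = -5), "tsum1")
  expect_error(crop_params(smw = 0.5), "smw < smfcf")
  expect_error(crop_params(span = 0), "span")
  expect_error(crop_params(nonsense = 1), "unknown parameter")
  bad_fltb <- data.frame(dvs = c(0, 0.5, 1, 1.3, 2),
                         value = c(0.5, 0.62, 0.18, 0.12, 0.05))
  expect_error(crop_params(fltb = bad_fltb), "interpolate to 1")
})

test_that("stress factors hit their analytic anchor points", {
  p <- crop_params()
  expect_equal(stress_factors(p$smw, default_san(), p)$f_water, 0)
  expect_equal(stress_factors(p$smfcf, default_san(), p)$f_water, 1)
  expect_equal(stress_factors(0.6, default_san(), p)$f_water, 1)
  mid <- (p$smw + p$smfcf) / 2
  expect_equal(stress_factors(mid, default_san(), p)$f_water, 0.5)
  # half-saturation by construction: n = h_n, others saturating
  san <- list(n_avail = p$h_n, p_avail = 1e6, k_avail = 1e6)
  expect_equal(stress_factors(0.6, san, p)$f_nutrient, 0.5, tolerance = 1e-6)
  p_bad <- p; p_bad$smfcf <- p_bad$smw
  expect_error(stress_factors(0.3, default_san(), p_bad), "configuration")
})

test_that("a day without radiation or water changes no pools", {
  p <- crop_params()
  st <- init_crop_state(p)
  # radiation = 0, no cohort old enough to die
  out <- advance_day(st, list(doy = 141, tmin = 12, tmax = 24,
                              radiation = 0, precip = 0),
                     list(f_water = 1, f_nutrient = 1), p)
  expect_equal(out$lai_green, st$lai_green)
  expect_equal(out$w_stem, 0)
  # f_water = 0 shuts growth off exactly
  out2 <- advance_day(st, list(doy = 141, tmin = 12, tmax = 24,
                               radiation = 20, precip = 0),
                      list(f_water = 0, f_nutrient = 1), p)
  expect_equal(out2$w_leaf, st$w_leaf)
  expect_equal(out2$assim_in, 0)
})

test_that("a cohort aging past its span moves its area to brown LAI", {
  p <- crop_params()
  st <- init_crop_state(p)
  st$cohort_age <- p$span - 0.1
  contrib <- st$cohort_lai
  # tmax = tmin = 35 gives teff = 27, i.e. exactly one day at 35 degC
  out <- advance_day(st, list(doy = 141, tmin = 35, tmax = 35,
                              radiation = 0, precip = 0),
                     list(f_water = 1, f_nutrient = 1), p)
  expect_equal(out$lai_green, st$lai_green - contrib)
  expect_equal(out$lai_brown, contrib)
})

test_that("season simulation is deterministic with consistent state", {
  p <- crop_params()
  w <- season_weather()
  s1 <- simulate_season(p, w, default_san())
  s2 <- simulate_season(p, w, default_san())
  expect_identical(s1$trajectory, s2$trajectory)
  tr <- s1$trajectory
  expect_true(all(diff(tr$dvs) >= 0))
  expect_true(all(tr$lai_green >= 0))
  expect_equal(s1$final_state$lai_green, sum(s1$final_state$cohort_lai))
  expect_error(simulate_season(p, w[0, ], default_san()), "empty")
})

test_that("first day at DVS 1 is the first day thermal time reaches tsum1", {
  p <- crop_params()
  w <- season_weather()
  tr <- simulate_season(p, w, default_san())$trajectory
  teff <- pmax(0, (w$tmax + w$tmin) / 2 - p$tbase)
  expect_equal(which(tr$dvs >= 1)[1L], which(cumsum(teff) >= p$tsum1)[1L])
})

test_that("short phenology reaches maturity before season end", {
  p <- crop_params(tsum1 = 400, tsum2 = 300)
  tr <- simulate_season(p, season_weather(), default_san())$trajectory
  expect_lt(which(tr$dvs >= 2)[1L], nrow(tr))
})

test_that("more light-use efficiency and richer soil raise peak LAI", {
  w <- season_weather()
  peak <- function(p, san) max(simulate_season(p, w, san)$trajectory$lai_green)
  expect_gt(peak(crop_params(lue = 44), default_san()),
            peak(crop_params(lue = 22), default_san()))
  rich <- list(n_avail = 410, p_avail = 80, k_avail = 340)
  poor <- list(n_avail = 40, p_avail = 10, k_avail = 20)
  expect_gt(peak(crop_params(), rich), peak(crop_params(), poor))
})

test_that("assimilate converted into pools balances exactly", {
  p <- crop_params()
  s <- simulate_season(p, season_weather(), default_san())
  fs <- s$final_state
  gained <- (fs$w_leaf - init_crop_state(p)$w_leaf) + fs$w_stem +
    fs$w_storage + fs$w_root
  expect_equal(gained, fs$pool_out, tolerance = 1e-9)
})

test_that("LAI rescaling scales cohorts exactly and handles edge cases", {
  p <- crop_params()
  s <- simulate_season(p, season_weather()[1:60, ], default_san())
  st <- s$final_state
  expect_identical(rescale_lai(st, st$lai_green), st)
  doubled <- rescale_lai(st, 2 * st$lai_green)
  expect_equal(sum(doubled$cohort_lai), 2 * st$lai_green, tolerance = 1e-12)
  expect_equal(doubled$w_leaf, 2 * st$w_leaf)
  expect_equal(doubled$cohort_age, st$cohort_age)  # ages untouched
  gone <- rescale_lai(st, 0)
  expect_length(gone$cohort_lai, 0)
  expect_equal(gone$lai_green, 0)
  reborn <- rescale_lai(gone, 0.4)
  expect_equal(reborn$lai_green, 0.4)
  expect_equal(reborn$cohort_age, 0)
  expect_error(rescale_lai(st, -1), ">= 0")
})
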