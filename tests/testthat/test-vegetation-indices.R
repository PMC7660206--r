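test_that("vegetation indices evaluate their defining formulas", {
  b <- function(nir, red, green = 0.08)
    list(blue = 0.04, green = green, red = red, rededge = 0.2, nir = nir)

  expect_equal(compute_vi(b(0.3, 0.3), "NDVI"), 0)
  expect_equal(compute_vi(b(0.3, 0.3), "RVI"), 1)
  expect_equal(compute_vi(b(0.5, 0.1), "OSAVI"), 1.16 * 0.4 / 0.76,
               tolerance = 1e-12)
  expect_equal(compute_vi(b(0.5, 0.1), "EVI2"),
               2.5 * 0.4 / (0.5 + 2.4 * 0.1 + 1), tolerance = 1e-12)
  nir <- 0.4; red <- 0.08; green <- 0.1
  expect_equal(compute_vi(b(nir, red, green), "MTVI2"),
               1.5 * (1.2 * (nir - green) - 2.5 * (red - green)) /
                 sqrt((2 * nir + 1)^2 - (6 * nir - 5 * sqrt(red)) - 0.5),
               tolerance = 1e-12)
})

test_that("undefined index values raise errors", {
  b <- list(blue = 0.04, green = 0.08, red = 0, rededge = 0.2, nir = 0)
  expect_error(compute_vi(b, "NDVI"), "NIR \\+ RED")
  expect_error(compute_vi(b, "RVI"), "RED = 0")
  expect_error(compute_vi(list(blue = 0.1, green = 0.2, red = 1, rededge = 0.2,
                               nir = 1.2), "NDVI"), "\\[0, 1\\]")
})

test_that("NDVI stays in [-1,1] and OSAVI shares its sign", {
  set.seed(11)
  for (i in 1:200) {
    b <- list(blue = runif(1), green = runif(1), red = runif(1, 0.01, 1),
              rededge = runif(1), nir = runif(1, 0.01, 1))
    ndvi <- compute_vi(b, "NDVI")
    expect_gte(ndvi, -1); expect_lte(ndvi, 1)
    expect_gte(sign(compute_vi(b, "OSAVI")) * sign(ndvi), 0)
  }
})

test_that("linear model fitting matches the normal-equations oracle", {
  # exact line is recovered
  vi <- c(0.1, 0.3, 0.5, 0.8)
  m <- fit_linear_model(vi, 4 * vi + 0.5)
  expect_equal(m$a, 4, tolerance = 1e-10)
  expect_equal(m$b, 0.5, tolerance = 1e-10)
  expect_equal(abs(m$r), 1, tolerance = 1e-10)

  # three printed points against the closed form
  o <- ols_oracle(c(1, 2, 3), c(1, 2, 4))
  m3 <- fit_linear_model(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m3$a, o$a, tolerance = 1e-10)  # 3/2
  expect_equal(m3$b, o$b, tolerance = 1e-10)  # -2/3
  expect_equal(m3$r, o$r, tolerance = 1e-10)
  expect_equal(m3$a, 1.5); expect_equal(m3$b, -2 / 3)

  # uncorrelated noise has |r| near zero
  set.seed(5)
  mn <- fit_linear_model(rnorm(500), rnorm(500))
  expect_lt(abs(mn$r), 0.15)

  expect_error(fit_linear_model(rep(0.4, 5), 1:5), "constant")
  expect_error(fit_linear_model(1:4, 1:3), "equal length")
})

test_that("fitted correlation equals the closed form over random draws", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(10); y <- 2 * x + rnorm(10)
    expect_equal(fit_linear_model(x, y)$r, ols_oracle(x, y)$r,
                 tolerance = 1e-10)
  }
})

test_that("index selection follows |r| with definition-order tie-break", {
  mk <- function(r_vals) {
    ms <- Map(function(ix, r) structure(list(index_name = ix, r = r),
                                        class = "lai_vi_model"),
              vi_names(), r_vals)
    names(ms) <- vi_names()
    ms
  }
  # printed per-date correlation vectors
  expect_equal(select_best_vi(mk(c(0.78, 0.79, 0.75, 0.67, 0.73))), "RVI")
  expect_equal(select_best_vi(mk(c(0.63, 0.64, 0.55, 0.46, 0.39))), "RVI")
  expect_equal(select_best_vi(mk(c(0.30, 0.30, 0.42, 0.44, 0.33))), "EVI2")
  # ties resolve in definition order
  expect_equal(select_best_vi(mk(rep(0.5, 5))), "NDVI")
  expect_error(select_best_vi(list()), "no models")
})

test_that("correlation significance classes match the t test", {
  expect_equal(significance_class(0.79, 36), "**")
  expect_equal(significance_class(0.44, 29), "*")
  expect_equal(significance_class(0, 30), "ns")
  expect_equal(significance_class(1, 10), "**")
  expect_equal(significance_class(-0.79, 36), "**")
  # monotone in |r| for fixed n
  lv <- function(cls) match(cls, c("ns", "*", "**"))
  for (n in c(10, 29, 36)) {
    cls <- vapply(seq(0, 0.99, by = 0.01), significance_class,
                  character(1), n = n)
    expect_true(all(diff(lv(cls)) >= 0))
  }
})

test_that("LAI mapping applies the model, clamps negatives and masks", {
  # NDVI = 0.5 (exact dyadic bands) and 0.3 rows
  refl <- data.frame(blue = 0.04, green = 0.08, red = c(0.125, 0.07),
                     rededge = 0.2, nir = c(0.375, 0.13))
  ident <- structure(list(index_name = "NDVI", a = 1, b = 0),
                     class = "lai_vi_model")
  expect_equal(as.numeric(estimate_lai_map(refl, ident)), c(0.5, 0.3),
               tolerance = 1e-12)
  clampm <- structure(list(index_name = "NDVI", a = 2, b = -1),
                      class = "lai_vi_model")
  out <- estimate_lai_map(refl, clampm)
  expect_equal(as.numeric(out), c(0, 0))  # 2*0.5-1 = 0; 2*0.3-1 clamped
  expect_equal(attr(out, "n_clamped"), 1L)

  # fitted model applied to training data reproduces fitted values
  set.seed(9)
  refl2 <- data.frame(blue = 0.04, green = 0.08,
                      red = runif(8, 0.05, 0.12), rededge = 0.2,
                      nir = runif(8, 0.2, 0.45))
  vi <- compute_vi(refl2, "NDVI")
  lai <- 3 * vi + 0.2 + rnorm(8, 0, 0.05)
  m <- fit_linear_model(vi, lai, "NDVI")
  expect_equal(as.numeric(estimate_lai_map(refl2, m)), m$a * vi + m$b,
               tolerance = 1e-10)
})
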