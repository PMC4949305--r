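## Insulin production, meal sources and liver saturation functions.

test_that("erf insulin production has the sigmoid's symmetry and limits", {
  p <- mf_params(overrides = list(v = 1.3, c = 0.6),
                 calibrate = FALSE)
  expect_equal(insulin_production(p$v, p, model = "erf"), p$k_1)
  expect_equal(insulin_production(p$v + 50 * p$c, p, model = "erf"),
               p$k_1 + p$k_2, tolerance = 1e-12)
  expect_true(all(diff(insulin_production(seq(0, 3, 0.1), p,
                                          model = "erf")) > 0))
})

test_that("erf production at one width above threshold matches a series oracle", {
  p <- mf_params(overrides = list(k_1 = 1, k_2 = 1), calibrate = FALSE)
  got <- insulin_production(p$v + p$c, p, model = "erf")
  expect_equal(got, 1 + erf_series(1), tolerance = 1e-12)
})

test_that("quadratic insulin production is polynomial and monotone", {
  p <- mf_params(overrides = list(k_IG = 2, k_I2 = 3), calibrate = FALSE)
  expect_identical(insulin_production(0, p, model = "quadratic"), 0)
  expect_equal(insulin_production(1, p, model = "quadratic"), 5)
  expect_gt(insulin_production(2, p, model = "quadratic"),
            insulin_production(1, p, model = "quadratic"))
})

test_that("insulin production rejects invalid input", {
  p <- cached_params()
  expect_error(insulin_production(NaN, p), "non-finite")
  expect_error(insulin_production(-0.1, p), "non-negative")
  expect_error(insulin_production(1, mf_params(overrides = list(c = 1e-12),
                                               calibrate = FALSE),
                                  model = "erf"), NA)
  p2 <- mf_params(calibrate = FALSE)
  p2$c <- 0
  expect_error(insulin_production(1, p2, model = "erf"), "c must be > 0")
})

test_that("meal sources vanish at t = 0 and peak at the delay time", {
  p <- cached_params()
  expect_equal(unname(meal_sources(0, p)[1, ]), c(0, 0))
  ## grid-search oracle for the peak position and the calculus value there
  tg <- seq(1e-4, 6, length.out = 20000)
  FG <- meal_sources(tg, p)[, "F_G"]
  expect_equal(tg[which.max(FG)], p$B_G, tolerance = 1e-3)
  expect_equal(max(FG), p$F * p$theta_G / p$B_G * exp(-0.5),
               tolerance = 1e-6)
  FT <- meal_sources(tg, p)[, "F_T"]
  expect_equal(tg[which.max(FT)], p$B_T, tolerance = 1e-3)
})

test_that("meal sources integrate to the delivered meal fractions", {
  p <- cached_params()
  qg <- integrate(function(t) meal_sources(t, p)[, "F_G"], 0, 20 * p$B_G,
                  rel.tol = 1e-10)
  qt <- integrate(function(t) meal_sources(t, p)[, "F_T"], 0, 20 * p$B_T,
                  rel.tol = 1e-10)
  expect_equal(qg$value, p$F * p$theta_G, tolerance = 1e-6)
  expect_equal(qt$value, p$F * p$theta_T, tolerance = 1e-6)
})

test_that("meal sources reject non-positive delays and negative times", {
  p <- mf_params(calibrate = FALSE)
  p$B_G <- 0
  expect_error(meal_sources(1, p), "B_G and B_T")
  expect_error(meal_sources(-1, cached_params()), ">= 0")
})

test_that("saturation functions obey their bounds and monotonicity", {
  p <- cached_params()
  f <- saturation_functions(0, 0, p)
  expect_equal(f$f1, 0)
  expect_equal(f$f3, 0)
  expect_equal(saturation_functions(p$Y_max, 1, p)$f2, 0)
  expect_equal(saturation_functions(p$Y_0, 1, p)$f1, 0.5)
  yl <- seq(0, p$Y_max, length.out = 50)
  f1 <- vapply(yl, function(y) saturation_functions(y, 1, p)$f1, 1)
  f2 <- vapply(yl, function(y) saturation_functions(y, 1, p)$f2, 1)
  f3 <- vapply(yl, function(y) saturation_functions(1, y, p)$f3, 1)
  expect_true(all(diff(f1) > 0) && all(diff(f3) > 0))
  expect_true(all(diff(f2) < 0))
  expect_true(all(c(f1, f2, f3) >= 0 & c(f1, f2, f3) < 1))
  expect_error(saturation_functions(p$Y_max + 1e-6, 1, p), "cap")
})
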