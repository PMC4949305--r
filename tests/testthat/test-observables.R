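## Derived observables and trajectory summaries.

test_that("fractional glucose oxidation is gated by insulin and substrates", {
  p <- cached_params()
  s <- mf_sensitivities()
  st <- unity_state(); st[["I"]] <- 0
  expect_identical(fractional_glucose_oxidation(st, p, s), 0)
  st <- unity_state(); st[["A_m"]] <- 0
  expect_identical(fractional_glucose_oxidation(st, p, s), 1)
  ## state engineered so the weighted fluxes are equal
  st <- unity_state()
  st[["A_m"]] <- p$gamma_g * s[["sigma_G"]] * p$M_G / (p$gamma_a * p$M_A)
  expect_equal(fractional_glucose_oxidation(st, p, s), 0.5)
  ## zero-substrate convention
  st <- unity_state(); st[["A_m"]] <- 0; st[["G_m"]] <- 0
  expect_identical(fractional_glucose_oxidation(st, p, s), 0)
})

test_that("the unweighted oxidation fraction drops the AMP stoichiometries", {
  p <- cached_params()
  s <- mf_sensitivities()
  st <- unity_state()
  got <- fractional_glucose_oxidation(st, p, s, gamma_weighted = FALSE)
  expect_equal(got, p$M_G / (p$M_G + p$M_A))
})

test_that("adipose TAG clearance is linear in plasma TAG and lower under resistance", {
  p <- cached_params()
  s <- mf_sensitivities()
  st <- unity_state(); st[["T_b"]] <- 0
  expect_identical(adipose_tag_clearance(st, p, s), 0)
  st1 <- unity_state(); st2 <- unity_state(); st2[["T_b"]] <- 2
  expect_equal(adipose_tag_clearance(st2, p, s),
               2 * adipose_tag_clearance(st1, p, s))
  ir <- scenario_sensitivities("adipose")
  expect_lt(adipose_tag_clearance(st1, p, ir),
            adipose_tag_clearance(st1, p, s))
})

test_that("a constant unity trajectory summarises to the trivial baseline", {
  tr <- cached_run("healthy", t_end = 1)
  flat <- tr
  flat[names(unity_state())] <- 1
  flat$frac_glucose_oxidation <- flat$frac_glucose_oxidation[1]
  flat$adipose_tag_clearance <- flat$adipose_tag_clearance[1]
  s <- summarise_trajectory(flat)
  expect_equal(s$net_hepatic_TAG_gain, 0)
  expect_equal(s$flexibility_range, 0)
  expect_lte(s$recovery_time, 1 / 60)
  expect_true(s$recovered)
  expect_identical(s$n_glucose_peaks, 0L)
})

test_that("summaries are stable under grid refinement", {
  p <- cached_params()
  a <- summarise_trajectory(mf_simulate(p, t_end = 6, dt = 1 / 60))
  b <- summarise_trajectory(mf_simulate(p, t_end = 6, dt = 1 / 120))
  for (f in c("net_hepatic_TAG_gain", "flexibility_range"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-4)
  expect_equal(a$peaks[["G_b"]], b$peaks[["G_b"]], tolerance = 1e-4)
  expect_equal(a$total_oxidation, b$total_oxidation, tolerance = 1e-4)
  expect_identical(a$n_glucose_peaks, b$n_glucose_peaks)
})

test_that("the prominent-maxima detector separates genuine double spikes", {
  t <- seq(0, 6, by = 1 / 60)
  one <- exp(-(t - 1)^2)
  two <- exp(-(t - 1)^2 / 0.1) + 0.9 * exp(-(t - 2)^2 / 0.1)
  ripple <- one + 1e-5 * sin(40 * t)      # sub-threshold wiggles
  expect_length(metaflex:::prominent_maxima(t, one), 1L)
  expect_length(metaflex:::prominent_maxima(t, two), 2L)
  expect_length(metaflex:::prominent_maxima(t, ripple), 1L)
})

test_that("summaries refuse a window shorter than required", {
  tr <- cached_run("healthy", t_end = 1)
  expect_error(summarise_trajectory(tr, min_window = 12), "window")
})

test_that("scenario comparison rows match standalone runs", {
  p <- cached_params()
  cmp <- compare_scenarios(c("healthy", "muscle"), params = p, t_end = 6)
  solo <- summarise_trajectory(
    mf_simulate(p, scenario_sensitivities("healthy"), t_end = 6))
  i <- match("healthy", cmp$scenario)
  expect_equal(cmp$peak_G_b[i], solo$peaks[["G_b"]], tolerance = 1e-12)
  expect_equal(cmp$net_hepatic_TAG_gain[i], solo$net_hepatic_TAG_gain,
               tolerance = 1e-12)
  expect_equal(cmp$flexibility_range[i], solo$flexibility_range,
               tolerance = 1e-12)
})
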