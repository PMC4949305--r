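## Structural fidelity of the named-flux decomposition.

test_that("insulin-gated fluxes vanish when insulin is zero", {
  p <- cached_params()
  st <- unity_state(); st[["I"]] <- 0
  fl <- compute_fluxes(st, 0, p, mf_sensitivities())
  expect_identical(unname(fl[["hepatic_glucose_uptake"]]), 0)
  expect_identical(unname(fl[["lipogenesis"]]), 0)
  expect_identical(unname(fl[["hepatic_TAG_synthesis"]]), 0)
  expect_identical(unname(fl[["muscle_glucose_oxidation"]]), 0)
})

test_that("all fluxes are finite and non-negative on random non-negative states", {
  p <- cached_params()
  states <- random_states(50, p, seed = 7)
  for (sc in c("healthy", "all")) {
    s <- scenario_sensitivities(sc)
    for (i in seq_len(nrow(states))) {
      fl <- compute_fluxes(states[i, ], 0.5, p, s)
      expect_true(all(is.finite(fl)) && all(fl >= 0))
    }
  }
})

test_that("flux-assembled vector field matches a direct transcription", {
  p <- cached_params()
  states <- random_states(100, p, seed = 1)
  for (model in c("quadratic", "erf")) {
    pm <- calibrate_to_unity_steady_state(p, insulin_model = model)
    for (sc in c("healthy", "adipose", "liver", "muscle", "all")) {
      s <- scenario_sensitivities(sc)
      t <- 0.7
      err <- vapply(seq_len(nrow(states)), function(i) {
        a <- mf_rhs(states[i, ], t, pm, s, insulin_model = model)
        b <- rhs_direct(states[i, ], t, pm, s, model = model)
        max(abs(a - b))
      }, numeric(1))
      expect_lt(max(err), 1e-12)
    }
  }
})

test_that("every transport flux cancels between its two compartments", {
  ## multiplying each equation by its volume factor, compartment-pair sums
  ## must contain no transport terms; the residual sums are expressible in
  ## the remaining (source/sink) fluxes alone
  p <- cached_params()
  s <- scenario_sensitivities("liver+muscle")
  states <- random_states(100, p, seed = 2)
  for (i in seq_len(nrow(states))) {
    y <- states[i, ]
    t <- 1.2
    d <- mf_rhs(y, t, p, s)
    fl <- compute_fluxes(y, t, p, s)
    w <- volume_factors(p) * d
    ## plasma glucose + hepatic glycogen: uptake/output pair cancels
    expect_equal(w[["G_b"]] + w[["Y_L"]],
                 -fl[["body_glucose_sink"]] - fl[["muscle_glucose_uptake"]] -
                   fl[["lipogenesis"]] + fl[["meal_glucose_input"]],
                 tolerance = 1e-12)
    ## plasma glucose + whole muscle glucose pool: muscle uptake cancels
    expect_equal(w[["G_b"]] + w[["Y_L"]] + w[["G_m"]] + w[["Y_m"]],
                 -fl[["body_glucose_sink"]] - fl[["lipogenesis"]] -
                   fl[["muscle_glucose_oxidation"]] +
                   fl[["meal_glucose_input"]],
                 tolerance = 1e-12)
    ## plasma TAG + hepatic TAG: hepatic output pair cancels
    expect_equal(w[["T_b"]] + w[["T_L"]],
                 fl[["hepatic_TAG_synthesis"]] - fl[["muscle_TAG_uptake"]] -
                   fl[["adipose_TAG_uptake"]] + fl[["meal_TAG_input"]],
                 tolerance = 1e-12)
    ## plasma FFA + hepatic FFA: both exchange fluxes cancel
    expect_equal(w[["A_b"]] + w[["A_L"]],
                 fl[["adipose_FFA_output"]] - fl[["muscle_FFA_uptake"]] +
                   fl[["lipogenesis"]] - fl[["hepatic_FFA_oxidation"]] -
                   fl[["hepatic_TAG_synthesis"]],
                 tolerance = 1e-12)
    ## muscle glucose + glycogen: synthesis/glycogenolysis antisymmetric
    expect_equal(w[["G_m"]] + w[["Y_m"]],
                 fl[["muscle_glucose_uptake"]] -
                   fl[["muscle_glucose_oxidation"]],
                 tolerance = 1e-12)
    ## muscle FFA + TAG: synthesis/lipolysis antisymmetric
    expect_equal(w[["A_m"]] + w[["T_m"]],
                 fl[["muscle_TAG_uptake"]] + fl[["muscle_FFA_uptake"]] -
                   fl[["muscle_FFA_oxidation"]],
                 tolerance = 1e-12)
  }
})

test_that("fluxes respond monotonically to the sensitivity factors", {
  p <- cached_params()
  st <- unity_state(); st[["I"]] <- 1.5
  h <- 1e-6
  flux_at <- function(name, ...) {
    compute_fluxes(st, 0, p, mf_sensitivities(...),
                   meal = FALSE)[[name]]
  }
  ## muscle glucose uptake increases with sigma_G
  expect_gt(flux_at("muscle_glucose_uptake", sigma_G = 0.5 + h),
            flux_at("muscle_glucose_uptake", sigma_G = 0.5))
  ## adipose FFA output increases as sigma_A decreases (release of
  ## insulin suppression)
  expect_gt(flux_at("adipose_FFA_output", sigma_A = 0.5),
            flux_at("adipose_FFA_output", sigma_A = 0.5 + h))
  ## hepatic glucose output increases as sigma_L decreases
  expect_gt(flux_at("hepatic_glucose_output", sigma_L = 0.5),
            flux_at("hepatic_glucose_output", sigma_L = 0.5 + h))
})

test_that("invalid states are rejected and small cap overshoot is clamped", {
  p <- cached_params()
  bad <- unity_state(); bad[["A_m"]] <- -0.1
  expect_error(compute_fluxes(bad, 0, p, mf_sensitivities()), "negative")
  over <- unity_state(); over[["Y_L"]] <- p$Y_max + 1e-10
  expect_silent(compute_fluxes(over, 0, p, mf_sensitivities()))
  far <- unity_state(); far[["Y_L"]] <- p$Y_max + 1e-3
  expect_error(compute_fluxes(far, 0, p, mf_sensitivities()), "Y_max")
})
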