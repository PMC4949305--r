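## Fasting-state calibration and fasting baselines.

#' Calibrate the model to the unity fasting state
#'
#' Solves the coefficients marked `"calibrated"` in the registry so that the
#' unity state (all scaled concentrations equal 1, meal off, healthy
#' sensitivities) is the fasting reference state.  One coefficient is
#' designated per balance equation:
#' insulin degradation `lambda_I`; hepatic basal glucose output `beta_G`
#' (plasma glucose); TAG saturation constant `T_0` (plasma TAG); muscle FFA
#' uptake `k_A` (plasma FFA); plasma-to-liver FFA uptake `k_BL` (hepatic
#' FFA); hepatic TAG synthesis `k_TH` (hepatic TAG); AMP production `mu`;
#' glucose oxidation `M_G` (muscle glucose); glycogenolysis `k_CP` (muscle
#' glycogen); FFA oxidation `M_A` (muscle FFA); TAG lipolysis `k_DP`
#' (muscle TAG).  Parameters taken from the literature tables are never
#' altered.
#'
#' The hepatic glycogen balance cannot be closed simultaneously with the
#' plasma glucose balance: with the glycogen equation at equilibrium,
#' hepatic output equals hepatic uptake, and the plasma balance would then
#' require the whole-body sink, muscle uptake and lipogenesis to vanish.
#' This is the model's rendering of a real feature of fasting physiology —
#' the body's glucose consumption is met by a slow drain of liver glycogen.
#' Calibration therefore balances the plasma equation exactly and reports
#' the irreducible glycogen drift
#' `-(S_G + k_G (1 + k_GI) + k_AL) / eta` (per hour) in the
#' `fasting_drift` attribute; all other eleven equations have zero residual
#' at the unity state.
#'
#' @param params `mf_params`, possibly with unresolved (`NA`) calibrated
#'   coefficients.
#' @param insulin_model Optional override of the insulin production form
#'   used to pin `lambda_I`.
#' @return Calibrated `mf_params` (idempotent: recalibrating changes
#'   nothing).
#' @export
#' @examples
#' p <- mf_params(calibrate = FALSE)
#' p <- calibrate_to_unity_steady_state(p)
#' r <- mf_rhs(unity_state(), 0, p, mf_sensitivities(), meal = FALSE)
#' max(abs(r[setdiff(names(r), "Y_L")]))   # ~ 1e-16
calibrate_to_unity_steady_state <- function(params, insulin_model = NULL) {
  p <- params
  if (is.null(insulin_model)) insulin_model <- attr(p, "insulin_model")
  fail <- function(eq, why)
    stop("calibration failure in the ", eq, " equation: ", why,
         call. = FALSE)

  ## muscle glucose: fasting oxidation balances fasting uptake
  p$M_G <- p$k_G * (1 + p$k_GI)
  if (p$M_G <= 0) fail("muscle glucose", "k_G (1 + k_GI) must be > 0")
  ## muscle glycogen: synthesis = glycogenolysis at unity
  p$k_CP <- p$k_Y * (1 + p$k_YI) / (1 + p$k_YP) * (1 + p$k_CI)
  ## plasma glucose: hepatic output supplies uptake + sink + muscle + DNL
  if (p$Y_max <= 1)
    fail("hepatic glycogen", "capacity Y_max must exceed the fasting level 1")
  f1s <- 1 / (p$Y_0 + 1)
  f2s <- (p$Y_max - 1) / (p$Y_0 + p$Y_max - 1)
  hgu <- p$k_L * f2s
  drain <- p$S_G + p$M_G + p$k_AL
  p$beta_G <- (hgu + drain) * (1 + p$k_GL) / f1s
  ## plasma TAG: hepatic output balances muscle + adipose clearance
  hto <- p$k_T + p$k_TA * (1 + p$k_AI)
  f3s <- hto * (1 + p$k_TL) / p$beta_T
  if (f3s <= 0 || f3s >= 1)
    fail("plasma TAG", paste0("basal output beta_T = ", p$beta_T,
         " cannot supply the fasting clearance ", signif(hto, 6),
         " (requires beta_T > ", signif(hto * (1 + p$k_TL), 6), ")"))
  p$T_0 <- 1 / f3s - 1
  ## hepatic TAG: esterification balances output
  p$k_TH <- hto
  ## hepatic FFA: uptake balances release + oxidation + esterification - DNL
  p$k_BL <- p$k_LB + p$S_L / (1 + p$k_AS) + p$k_TH - p$k_AL
  if (p$k_BL < 0)
    fail("hepatic FFA", "lipogenesis exceeds hepatic FFA consumption")
  ## plasma FFA: adipose output + liver release balance muscle/liver uptake
  afo <- p$beta_A / (1 + p$k_AA)
  p$k_A <- afo + p$k_LB - p$k_BL
  if (p$k_A < 0)
    fail("plasma FFA", paste0("adipose basal output beta_A = ", p$beta_A,
         " too small to supply the hepatic FFA uptake"))
  ## muscle FFA: oxidation balances TAG + FFA uptake
  p$M_A <- p$k_T + p$k_A
  ## muscle TAG: synthesis = lipolysis at unity
  p$k_DP <- p$k_X * (1 + p$k_XI) / (1 + p$k_XP) * (1 + p$k_DI)
  ## AMP: production balances degradation + oxidative consumption
  p$mu <- p$lambda_P + p$gamma_a * p$M_A + p$gamma_g * p$M_G
  ## insulin: degradation balances production at unity
  p$lambda_I <- insulin_production(1, p, insulin_model) + p$k_IA

  prov <- attr(params, "provenance")
  for (nm in c("M_G", "k_CP", "beta_G", "T_0", "k_TH", "k_BL", "k_A",
               "M_A", "k_DP", "mu", "lambda_I"))
    prov[nm] <- "calibrated"
  attributes(p) <- attributes(params)
  attr(p, "provenance") <- prov
  attr(p, "insulin_model") <- insulin_model
  attr(p, "calibrated") <- TRUE
  attr(p, "fasting_drift") <- -drain / p$eta
  validate_params(p, allow_na = FALSE)
  p
}

#' Fasting baseline state
#'
#' Computes the fasting (meal-free) baseline of the model for a given
#' sensitivity configuration.  Because the printed kinetics have no interior
#' equilibrium of the full system (fasting glucose consumption is met by a
#' slow hepatic glycogen drain), the baseline is defined on the fast
#' subsystem: hepatic glycogen — the slow store — is held at its reference
#' value and the remaining eleven balances are solved to equilibrium by
#' damped (Levenberg–Marquardt) root finding seeded from the unity state.
#'
#' @param params Calibrated `mf_params`.
#' @param sens `mf_sens`; defaults to healthy.
#' @param insulin_model Optional override of the insulin production form.
#' @param Y_L Value at which the hepatic glycogen store is held (default 1).
#' @param tol Maximum acceptable residual of the solved balances.
#' @param check_stability Also compute the Jacobian of the reduced system
#'   and verify all eigenvalue real parts are negative.
#' @return Named 12-state vector with attributes `residual_max` and (if
#'   requested) `eigenvalues`.
#' @export
#' @examples
#' p <- mf_params()
#' steady_state(p)                                   # unity, by calibration
#' steady_state(p, scenario_sensitivities("adipose")) # lower fasting A_b
steady_state <- function(params, sens = mf_sensitivities(),
                         insulin_model = NULL, Y_L = 1, tol = 1e-10,
                         check_stability = FALSE) {
  if (!isTRUE(attr(params, "calibrated")))
    stop("parameters must be calibrated first", call. = FALSE)
  free <- setdiff(seq_along(mf_state_names), 5L)
  ## the liver equations carry a 1/eta factor that makes their raw
  ## residuals ill-scaled for least squares; solve the volume-weighted
  ## (flux-balance) form, which has the same root
  w <- c(1, params$alpha, params$alpha, params$alpha, params$eta,
         params$eta, params$eta, 1, 1, 1, 1, 1)[free]
  rhs_free <- function(x) {
    y <- numeric(12L)
    y[free] <- abs(x)          # reflection keeps the search non-negative
    y[5L] <- Y_L
    names(y) <- mf_state_names
    mf_rhs(y, 0, params, sens, insulin_model, meal = FALSE)[free]
  }
  resid <- function(x) w * rhs_free(x)
  ## seed the damped root finder from a short relaxation of the reduced
  ## system, so baselines far from unity (e.g. elevated fasting TAG under
  ## resistance) are reached reliably
  relax <- deSolve::ode(
    y = unity_state()[free], times = c(0, 200),
    func = function(t, y, parms) list(rhs_free(pmax(y, 0))),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  start <- pmax(as.numeric(relax[nrow(relax), -1L]), 1e-8)
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  y <- numeric(12L)
  y[free] <- abs(fit$par)
  y[5L] <- Y_L
  names(y) <- mf_state_names
  rmax <- max(abs(rhs_free(fit$par)))
  if (!is.finite(rmax) || rmax > tol)
    stop("fasting baseline did not converge: residual ", format(rmax),
         " exceeds ", format(tol), call. = FALSE)
  attr(y, "residual_max") <- rmax
  if (check_stability) {
    J <- reduced_jacobian(y, params, sens, insulin_model)
    ev <- eigen(J, only.values = TRUE)$values
    attr(y, "eigenvalues") <- ev
    attr(y, "stable") <- all(Re(ev) < 0)
  }
  y
}

## numerical Jacobian of the reduced (glycogen-frozen) vector field
reduced_jacobian <- function(y, params, sens, insulin_model = NULL,
                             h = 1e-7) {
  free <- setdiff(seq_along(mf_state_names), 5L)
  f0 <- mf_rhs(y, 0, params, sens, insulin_model, meal = FALSE)[free]
  J <- matrix(0, 11L, 11L)
  for (j in seq_along(free)) {
    yp <- y
    yp[free[j]] <- yp[free[j]] + h
    J[, j] <- (mf_rhs(yp, 0, params, sens, insulin_model,
                      meal = FALSE)[free] - f0) / h
  }
  J
}
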