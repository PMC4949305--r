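## Kinetic building blocks: insulin production, meal sources, liver
## saturation functions, and the named flux decomposition of the model.

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Insulin production rate
#'
#' Glucose-dependent pancreatic insulin production `f0(G_b)`.  Two forms are
#' provided: the sigmoidal error-function form
#' `k_1 + k_2 * erf((G_b - v)/c)`, and the quadratic approximation
#' `k_IG * G_b + k_I2 * G_b^2` used for the numerical work.  The plasma-FFA
#' contribution `k_IA * A_b` of the insulin balance is handled separately in
#' [compute_fluxes()].
#'
#' @param G_b Plasma glucose (dimensionless, >= 0).  Vectorised.
#' @param params `mf_params`.
#' @param model `"quadratic"` or `"erf"`; defaults to the model stored in
#'   `params`.
#' @return Production rate(s); for the erf form bounded in
#'   `[k_1 - k_2, k_1 + k_2]`.
#' @export
#' @examples
#' p <- mf_params()
#' insulin_production(1, p)
insulin_production <- function(G_b, params, model = NULL) {
  if (is.null(model)) model <- attr(params, "insulin_model")
  model <- match.arg(model, c("quadratic", "erf"))
  if (any(!is.finite(G_b)))
    stop("non-finite plasma glucose value", call. = FALSE)
  if (any(G_b < 0))
    stop("plasma glucose must be non-negative", call. = FALSE)
  if (model == "quadratic") {
    params$k_IG * G_b + params$k_I2 * G_b^2
  } else {
    if (!is.finite(params$c) || params$c <= 0)
      stop("erf width parameter c must be > 0", call. = FALSE)
    params$k_1 + params$k_2 * erf((G_b - params$v) / params$c)
  }
}

#' Meal source terms
#'
#' Dietary glucose and TAG delivery into the plasma after a meal eaten at
#' `t = 0`:
#' `F_G(t) = F * theta_G * t / B_G^2 * exp(-t^2 / (2 B_G^2))` and the
#' analogous `F_T(t)`.  `F_G` peaks at `t = B_G`, and the total delivered
#' glucose equals `F * theta_G` (fat: `F * theta_T`).
#'
#' @param t Time(s) in hours since the meal, `>= 0`.  Vectorised.
#' @param params `mf_params` (uses `F`, `theta_G`, `theta_T`, `B_G`, `B_T`).
#' @return Matrix with columns `F_G` and `F_T`.
#' @export
#' @examples
#' meal_sources(c(0, 0.75, 2), mf_params())
meal_sources <- function(t, params) {
  if (params$B_G <= 0 || params$B_T <= 0)
    stop("meal delay parameters B_G and B_T must be > 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("meal time must be finite and >= 0", call. = FALSE)
  FG <- params$F * params$theta_G * t / params$B_G^2 *
    exp(-t^2 / (2 * params$B_G^2))
  FT <- params$F * params$theta_T * t / params$B_T^2 *
    exp(-t^2 / (2 * params$B_T^2))
  cbind(F_G = FG, F_T = FT)
}

#' Liver saturation functions
#'
#' The three saturating factors regulating hepatic storage:
#' `f1 = Y_L/(Y_0 + Y_L)` (glycogen availability for glucose output),
#' `f2 = (Y_max - Y_L)/(Y_0 + Y_max - Y_L)` (remaining glycogen capacity;
#' zero at the cap) and `f3 = T_L/(T_0 + T_L)` (TAG availability).
#'
#' @param Y_L Hepatic glycogen in `[0, Y_max]`.
#' @param T_L Hepatic TAG, `>= 0`.
#' @param params `mf_params` (uses `Y_0`, `Y_max`, `T_0`).
#' @return List with elements `f1`, `f2`, `f3`, each in `[0, 1)`.
#' @export
saturation_functions <- function(Y_L, T_L, params) {
  if (any(Y_L < 0) || any(T_L < 0))
    stop("hepatic stores must be non-negative", call. = FALSE)
  if (any(Y_L > params$Y_max))
    stop("hepatic glycogen exceeds its capacity Y_max (cap breached)",
         call. = FALSE)
  list(f1 = Y_L / (params$Y_0 + Y_L),
       f2 = (params$Y_max - Y_L) / (params$Y_0 + params$Y_max - Y_L),
       f3 = T_L / (params$T_0 + T_L))
}

#' Named pathway fluxes
#'
#' Evaluates every transport and conversion rate of the reaction network at
#' a given state, as a named non-negative vector.  These are the individual
#' terms of the model equations; [mf_rhs()] assembles them into the vector
#' field, so each physical flux appears exactly once and enters its two
#' compartments with opposite signs.
#'
#' @param state Named state vector in the canonical order (see
#'   [unity_state()]).
#' @param t Time in hours (drives the meal source terms).
#' @param params Calibrated `mf_params`.
#' @param sens `mf_sens` sensitivity factors.
#' @param insulin_model Optional override of the insulin production form.
#' @param meal If `FALSE`, the meal sources are zero (fasting kinetics).
#' @param cap_tol Numerical tolerance by which `Y_L` may overshoot `Y_max`
#'   (it is then clamped); a larger breach is an error.
#' @return Named numeric vector of class `mf_fluxes`.
#' @export
#' @examples
#' fl <- compute_fluxes(unity_state(), 0, mf_params(), mf_sensitivities())
#' fl["hepatic_glucose_uptake"]
compute_fluxes <- function(state, t, params, sens,
                           insulin_model = NULL, meal = TRUE,
                           cap_tol = 1e-8) {
  if (length(state) != 12L)
    stop("state must have 12 components", call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state component", call. = FALSE)
  if (any(state < 0))
    stop("negative state component: ",
         paste(mf_state_names[state < 0], collapse = ", "), call. = FALSE)
  I <- state[[1L]]; G_b <- state[[2L]]; T_b <- state[[3L]]
  A_b <- state[[4L]]; Y_L <- state[[5L]]; A_L <- state[[6L]]
  T_L <- state[[7L]]; P <- state[[8L]]; G_m <- state[[9L]]
  Y_m <- state[[10L]]; A_m <- state[[11L]]; T_m <- state[[12L]]
  if (Y_L > params$Y_max) {
    if (Y_L - params$Y_max > cap_tol)
      stop("hepatic glycogen exceeds Y_max by more than the clamp ",
           "tolerance (", format(Y_L - params$Y_max), ")", call. = FALSE)
    Y_L <- params$Y_max
  }
  f <- saturation_functions(Y_L, T_L, params)
  ms <- if (meal) meal_sources(max(t, 0), params) else cbind(F_G = 0, F_T = 0)
  p <- params; s <- sens
  fl <- c(
    hepatic_glucose_uptake = p$k_L * s[["sigma_Y"]] * I * G_b * f$f2,
    hepatic_glucose_output = p$beta_G / (1 + s[["sigma_L"]] * p$k_GL * I^2) * f$f1,
    muscle_glucose_uptake  = p$k_G * (1 + s[["sigma_G"]] * p$k_GI * I) * G_b,
    body_glucose_sink      = p$S_G * G_b,
    lipogenesis            = p$k_AL * I * G_b,
    hepatic_TAG_output     = p$beta_T / (1 + s[["sigma_T"]] * p$k_TL * I) * f$f3,
    muscle_TAG_uptake      = p$k_T * T_b,
    adipose_TAG_uptake     = s[["phi_AT"]] * p$k_TA *
      (1 + s[["sigma_AT"]] * p$k_AI * I) * T_b,
    adipose_FFA_output     = s[["phi_A"]] * p$beta_A /
      (1 + s[["sigma_A"]] * p$k_AA * I^2),
    muscle_FFA_uptake      = p$k_A * A_b,
    hepatic_FFA_uptake     = p$k_BL * A_b,
    hepatic_FFA_output     = p$k_LB * A_L,
    hepatic_FFA_oxidation  = p$S_L * A_L / (1 + p$k_AS * I),
    hepatic_TAG_synthesis  = p$k_TH * I * A_L,
    muscle_glucose_oxidation = s[["sigma_G"]] * p$M_G * P * I * G_m,
    muscle_glycogen_synthesis = p$k_Y *
      (1 + s[["sigma_G"]] * p$k_YI * I) / (1 + p$k_YP * P) * G_m,
    muscle_glycogenolysis  = p$k_CP * P * Y_m /
      (1 + s[["sigma_G"]] * p$k_CI * I),
    muscle_FFA_oxidation   = p$M_A * P * A_m,
    muscle_TAG_synthesis   = p$k_X * (1 + p$k_XI * I) / (1 + p$k_XP * P) * A_m,
    muscle_TAG_lipolysis   = p$k_DP * P * T_m / (1 + p$k_DI * I),
    insulin_production     = insulin_production(G_b, params, insulin_model) +
      p$k_IA * A_b,
    insulin_degradation    = p$lambda_I * I,
    meal_glucose_input     = ms[[1L, "F_G"]],
    meal_TAG_input         = ms[[1L, "F_T"]],
    amp_production         = p$mu,
    amp_degradation        = p$lambda_P * P
  )
  class(fl) <- "mf_fluxes"
  fl
}

#' Model vector field
#'
#' Time derivatives of the twelve state variables, assembled strictly as
#' signed sums of the named fluxes of [compute_fluxes()] divided by the
#' left-hand-side volume factor (`alpha` for the plasma equations, `eta` for
#' the liver equations, 1 otherwise).  The AMP balance weights the two
#' muscle oxidation fluxes by their stoichiometric factors `gamma_g` and
#' `gamma_a`.
#'
#' @inheritParams compute_fluxes
#' @return Named numeric vector of the 12 time derivatives.
#' @export
#' @examples
#' p <- mf_params()
#' mf_rhs(unity_state(), 0, p, mf_sensitivities(), meal = FALSE)
mf_rhs <- function(state, t, params, sens, insulin_model = NULL,
                   meal = TRUE, cap_tol = 1e-8) {
  fl <- compute_fluxes(state, t, params, sens, insulin_model, meal, cap_tol)
  a <- params$alpha; e <- params$eta
  d <- c(
    I   = fl[["insulin_production"]] - fl[["insulin_degradation"]],
    G_b = (fl[["hepatic_glucose_output"]] - fl[["body_glucose_sink"]] -
             fl[["muscle_glucose_uptake"]] - fl[["hepatic_glucose_uptake"]] -
             fl[["lipogenesis"]] + fl[["meal_glucose_input"]]) / a,
    T_b = (fl[["hepatic_TAG_output"]] - fl[["muscle_TAG_uptake"]] -
             fl[["adipose_TAG_uptake"]] + fl[["meal_TAG_input"]]) / a,
    A_b = (fl[["adipose_FFA_output"]] - fl[["muscle_FFA_uptake"]] -
             fl[["hepatic_FFA_uptake"]] + fl[["hepatic_FFA_output"]]) / a,
    Y_L = (fl[["hepatic_glucose_uptake"]] -
             fl[["hepatic_glucose_output"]]) / e,
    A_L = (fl[["lipogenesis"]] - fl[["hepatic_FFA_oxidation"]] +
             fl[["hepatic_FFA_uptake"]] - fl[["hepatic_FFA_output"]] -
             fl[["hepatic_TAG_synthesis"]]) / e,
    T_L = (fl[["hepatic_TAG_synthesis"]] - fl[["hepatic_TAG_output"]]) / e,
    P   = fl[["amp_production"]] - fl[["amp_degradation"]] -
      params$gamma_a * fl[["muscle_FFA_oxidation"]] -
      params$gamma_g * fl[["muscle_glucose_oxidation"]],
    G_m = fl[["muscle_glucose_uptake"]] - fl[["muscle_glucose_oxidation"]] -
      fl[["muscle_glycogen_synthesis"]] + fl[["muscle_glycogenolysis"]],
    Y_m = fl[["muscle_glycogen_synthesis"]] - fl[["muscle_glycogenolysis"]],
    A_m = fl[["muscle_TAG_uptake"]] + fl[["muscle_FFA_uptake"]] -
      fl[["muscle_FFA_oxidation"]] - fl[["muscle_TAG_synthesis"]] +
      fl[["muscle_TAG_lipolysis"]],
    T_m = fl[["muscle_TAG_synthesis"]] - fl[["muscle_TAG_lipolysis"]]
  )
  d
}

## deSolve-facing wrapper: tolerates tiny negative excursions (clamped to 0)
## and glycogen cap overshoot up to `cap_tol`, both inevitable with adaptive
## steppers at finite tolerance.
rhs_desolve <- function(params, sens, insulin_model, meal, cap_tol) {
  force(params); force(sens); force(insulin_model); force(meal)
  function(t, y, parms) {
    y <- pmax(y, 0)
    if (y[[5L]] > params$Y_max) y[[5L]] <- params$Y_max
    list(mf_rhs(y, t, params, sens, insulin_model, meal, cap_tol))
  }
}
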