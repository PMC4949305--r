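## Postprandial simulation, observables and scenario summaries.

#' Meal specification
#'
#' A mixed meal given at `t = 0`.  The carbohydrate and fat energy contents
#' set the dietary fractions `theta_G = carb/(carb + fat)` and
#' `theta_T = fat/(carb + fat)`; `F` is the total meal magnitude on the
#' dimensionless model scale.
#'
#' @param carb_kcal Carbohydrate energy (kcal), default 550.
#' @param fat_kcal Fat energy (kcal), default 150.
#' @param F Dimensionless meal magnitude; `NULL` keeps the parameter-set
#'   default.
#' @return List of class `mf_meal`.
#' @export
#' @examples
#' mf_meal()            # the balanced 550/150 kcal reference meal
#' mf_meal(0, 0)        # fasting (no meal)
mf_meal <- function(carb_kcal = 550, fat_kcal = 150, F = NULL) {
  if (carb_kcal < 0 || fat_kcal < 0)
    stop("meal energy contents must be non-negative", call. = FALSE)
  tot <- carb_kcal + fat_kcal
  structure(list(carb_kcal = carb_kcal, fat_kcal = fat_kcal, F = F,
                 theta_G = if (tot > 0) carb_kcal / tot else 0,
                 theta_T = if (tot > 0) fat_kcal / tot else 0),
            class = "mf_meal")
}

#' Simulate a postprandial trajectory
#'
#' Integrates the model from the unity fasting state with the meal eaten at
#' `t = 0`, using adaptive stiff (`lsoda`, default) or explicit
#' (`ode45`) integration with dense output on a fixed grid.  The returned
#' trajectory carries the two derived observables used to compare
#' scenarios: fractional glucose oxidation (the metabolic-flexibility
#' readout) and adipose TAG clearance.
#'
#' @param params Calibrated `mf_params`.
#' @param sens `mf_sens` sensitivity factors (default healthy).
#' @param meal `mf_meal`; `mf_meal(0, 0)` turns the meal off.
#' @param t_end Duration in hours (default 12).
#' @param dt Output grid spacing in hours (default 1 minute).
#' @param method `"lsoda"` or `"ode45"`.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param insulin_model Optional override of the insulin production form.
#' @param from Initial state (default [unity_state()]).
#' @param gamma_weighted Weight the oxidation fluxes by their AMP
#'   stoichiometries in the fractional-oxidation observable.
#' @return Data frame of class `mf_trajectory` with columns `t`, the twelve
#'   state variables, `frac_glucose_oxidation` and `adipose_tag_clearance`;
#'   attributes `params`, `sens`, `meal`, `scenario` and `solver`.
#' @export
#' @examples
#' p <- mf_params()
#' tr <- mf_simulate(p, t_end = 2)
#' max(tr$G_b)
mf_simulate <- function(params, sens = mf_sensitivities(),
                        meal = mf_meal(), t_end = 12, dt = 1 / 60,
                        method = c("lsoda", "ode45"),
                        rtol = 1e-8, atol = 1e-10, insulin_model = NULL,
                        from = unity_state(), gamma_weighted = TRUE) {
  method <- match.arg(method)
  if (!isTRUE(attr(params, "calibrated")))
    stop("parameters must be calibrated first (see mf_params)",
         call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  p <- params
  if (!is.null(meal)) {
    stopifnot(inherits(meal, "mf_meal"))
    p$theta_G <- meal$theta_G
    p$theta_T <- meal$theta_T
    if (!is.null(meal$F)) p$F <- meal$F
    if (meal$carb_kcal + meal$fat_kcal == 0) p$F <- 0
  }
  times <- seq(0, t_end, by = dt)
  cap_tol <- 1e4 * atol
  fn <- rhs_desolve(p, sens, insulin_model, meal = p$F > 0, cap_tol)
  out <- deSolve::ode(y = from, times = times, func = fn, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed at t = ", format(max(out[, 1L])), call. = FALSE)
  states <- out[, 1L + seq_along(mf_state_names), drop = FALSE]
  if (min(states) < -10 * atol)
    stop("integration produced a negative concentration beyond tolerance",
         call. = FALSE)
  states[states < 0] <- 0
  breach <- max(states[, 5L]) - p$Y_max
  if (breach > cap_tol)
    stop("hepatic glycogen cap breached by ", format(breach), call. = FALSE)
  states[, 5L] <- pmin(states[, 5L], p$Y_max)
  tr <- data.frame(t = out[, 1L], states, check.names = FALSE)
  names(tr) <- c("t", mf_state_names)
  tr$frac_glucose_oxidation <-
    fractional_glucose_oxidation(states, p, sens, gamma_weighted)
  tr$adipose_tag_clearance <- adipose_tag_clearance(states, p, sens)
  attr(tr, "params") <- p
  attr(tr, "sens") <- sens
  attr(tr, "meal") <- meal
  attr(tr, "scenario") <- attr(sens, "scenario")
  attr(tr, "gamma_weighted") <- gamma_weighted
  attr(tr, "solver") <- list(method = method, rtol = rtol, atol = atol,
                             dt = dt,
                             steps = unname(attr(out, "istate")[3L]))
  class(tr) <- c("mf_trajectory", "data.frame")
  tr
}

#' Fractional glucose oxidation
#'
#' The share of skeletal-muscle substrate oxidation carried by glucose,
#' `x / (x + y)` with `x` the glucose oxidation flux and `y` the FFA
#' oxidation flux; with `gamma_weighted = TRUE` (default) the fluxes are
#' weighted by their AMP stoichiometries `gamma_g`, `gamma_a`.  By
#' convention the value is 0 when both fluxes vanish.  The range of this
#' quantity over a postprandial window is the model's measure of metabolic
#' flexibility.
#'
#' @param state Named 12-vector, or a matrix/data frame of states with the
#'   canonical columns.
#' @param params Calibrated `mf_params`.
#' @param sens `mf_sens`.
#' @param gamma_weighted Apply the AMP stoichiometric weights.
#' @return Fraction(s) in `[0, 1]`.
#' @export
fractional_glucose_oxidation <- function(state, params, sens,
                                         gamma_weighted = TRUE) {
  s <- as_state_matrix(state)
  x <- sens[["sigma_G"]] * params$M_G * s[, "P"] * s[, "I"] * s[, "G_m"]
  y <- params$M_A * s[, "P"] * s[, "A_m"]
  if (gamma_weighted) {
    x <- params$gamma_g * x
    y <- params$gamma_a * y
  }
  out <- ifelse(x + y > 0, x / (x + y), 0)
  unname(out)
}

#' Adipose TAG clearance
#'
#' The rate at which plasma TAG is taken up into adipose tissue,
#' `phi_AT * k_TA * (1 + sigma_AT * k_AI * I) * T_b`; strictly increasing
#' in both insulin and plasma TAG.
#'
#' @inheritParams fractional_glucose_oxidation
#' @return Clearance rate(s), non-negative.
#' @export
adipose_tag_clearance <- function(state, params, sens) {
  s <- as_state_matrix(state)
  unname(sens[["phi_AT"]] * params$k_TA *
           (1 + sens[["sigma_AT"]] * params$k_AI * s[, "I"]) * s[, "T_b"])
}

as_state_matrix <- function(state) {
  if (is.null(dim(state))) {
    if (length(state) != 12L) stop("state must have 12 components",
                                   call. = FALSE)
    state <- matrix(state, nrow = 1L,
                    dimnames = list(NULL, mf_state_names))
  }
  state <- as.matrix(state)
  if (is.null(colnames(state))) colnames(state) <- mf_state_names
  if (any(state < 0)) stop("negative state component", call. = FALSE)
  state
}

## prominent local maxima of a series: adjacent maxima must be separated by
## at least `min_sep` hours and by a dip of at least `min_dip_frac` of the
## global peak, else the lower one is discarded
prominent_maxima <- function(t, x, min_sep = 5 / 60, min_dip_frac = 1e-3) {
  dx <- diff(x)
  idx <- which(diff(sign(dx)) < 0) + 1L
  idx <- idx[x[idx] > x[1L]]          # ignore ripples below the start level
  if (!length(idx)) return(integer())
  thr <- min_dip_frac * max(x)
  repeat {
    if (length(idx) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      valley <- min(x[i:j])
      depth <- min(x[i], x[j]) - valley
      if (t[j] - t[i] < min_sep || depth < thr) {
        idx <- idx[-(k + if (x[i] >= x[j]) 1L else 0L)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  idx
}

#' Summarise a postprandial trajectory
#'
#' Computes the scenario summary: per-variable peaks and times of peak,
#' fasting (initial) values, net hepatic TAG gain over the window, the
#' metabolic-flexibility range (max minus min of fractional glucose
#' oxidation), total substrate oxidation (time integral of the AMP-weighted
#' oxidation fluxes), the number of prominent plasma-glucose maxima, and
#' the recovery time: the first time after the largest excursion at which
#' every state component stays within `recovery_tol` of its fasting value
#' for the rest of the window (`NA` with `recovered = FALSE` otherwise).
#'
#' @param traj `mf_trajectory`.
#' @param recovery_tol Relative band half-width for recovery (default 1%).
#' @param min_window Minimum window length (hours) the trajectory must
#'   cover.
#' @return List of class `mf_summary`.
#' @export
summarise_trajectory <- function(traj, recovery_tol = 0.01,
                                 min_window = NULL) {
  stopifnot(inherits(traj, "mf_trajectory"))
  if (!is.null(min_window) && max(traj$t) < min_window)
    stop("trajectory window (", max(traj$t), " h) shorter than required (",
         min_window, " h)", call. = FALSE)
  p <- attr(traj, "params")
  sens <- attr(traj, "sens")
  m <- as.matrix(traj[mf_state_names])
  fasting <- m[1L, ]
  peaks <- apply(m, 2L, max)
  t_peaks <- traj$t[apply(m, 2L, which.max)]
  troughs <- apply(m, 2L, min)
  dev <- abs(sweep(m, 2L, fasting, "-"))
  rel <- sweep(dev, 2L, pmax(abs(fasting), .Machine$double.eps), "/")
  sup <- apply(rel, 1L, max)
  i_peak <- which.max(sup)
  within <- rel <= recovery_tol
  all_within <- apply(within, 1L, all)
  ## must stay inside the band to the end of the window
  stays <- rev(cumprod(rev(all_within))) == 1
  cand <- which(stays & seq_along(stays) > i_peak)
  recovery_time <- if (length(cand)) traj$t[min(cand)] else NA_real_
  per_var_recovery <- vapply(seq_len(ncol(m)), function(j) {
    stays_j <- rev(cumprod(rev(within[, j]))) == 1
    ij <- which.max(dev[, j])
    cj <- which(stays_j & seq_along(stays_j) > ij)
    if (length(cj)) traj$t[min(cj)] else NA_real_
  }, numeric(1))
  names(per_var_recovery) <- mf_state_names
  fo <- traj$frac_glucose_oxidation
  ox <- sens[["sigma_G"]] * p$gamma_g * p$M_G *
    traj$P * traj$I * traj$G_m + p$gamma_a * p$M_A * traj$P * traj$A_m
  total_ox <- trapz(traj$t, ox)
  out <- list(
    scenario = attr(traj, "scenario"),
    t_end = max(traj$t),
    fasting = fasting,
    peaks = peaks,
    t_peaks = setNames(t_peaks, mf_state_names),
    troughs = troughs,
    net_hepatic_TAG_gain = unname(m[nrow(m), "T_L"] - m[1L, "T_L"]),
    flexibility_range = diff(range(fo)),
    total_oxidation = total_ox,
    peak_adipose_tag_clearance = max(traj$adipose_tag_clearance),
    n_glucose_peaks = length(prominent_maxima(traj$t, traj$G_b)),
    recovery_tol = recovery_tol,
    recovery_time = recovery_time,
    recovered = !is.na(recovery_time),
    per_variable_recovery = per_var_recovery
  )
  class(out) <- "mf_summary"
  out
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2)

#' @export
print.mf_summary <- function(x, ...) {
  cat("<mf_summary>", if (!is.null(x$scenario)) x$scenario else "",
      sprintf("(%g h window)\n", x$t_end))
  cat(sprintf("  peak G_b %.3f @ %.2f h | peak I %.3f | peak T_b %.3f | min A_b %.3f\n",
              x$peaks[["G_b"]], x$t_peaks[["G_b"]], x$peaks[["I"]],
              x$peaks[["T_b"]], x$troughs[["A_b"]]))
  cat(sprintf("  net hepatic TAG gain %+.3e | flexibility range %.3f | total oxidation %.3f\n",
              x$net_hepatic_TAG_gain, x$flexibility_range,
              x$total_oxidation))
  cat(sprintf("  glucose maxima: %d | recovery: %s\n", x$n_glucose_peaks,
              if (x$recovered) sprintf("%.2f h", x$recovery_time)
              else "not recovered"))
  invisible(x)
}

#' Compare insulin-resistance scenarios
#'
#' Runs the same meal protocol (shared parameters, solver and grid) for a
#' list of scenarios and tabulates their summaries.
#'
#' @param scenarios Character vector of scenario names (see
#'   [scenario_sensitivities()]).
#' @param params Calibrated `mf_params`.
#' @param meal `mf_meal`.
#' @param t_end,dt,method,rtol,atol Passed to [mf_simulate()].
#' @param recovery_tol Passed to [summarise_trajectory()].
#' @param ... Passed to [scenario_sensitivities()] (variant switches).
#' @return Data frame with one row per scenario and the scalar summary
#'   columns; the full summaries are attached as attribute `summaries` and
#'   the trajectories as attribute `trajectories`.
#' @export
#' @examples
#' \donttest{
#' cmp <- compare_scenarios(c("healthy", "muscle"), mf_params(), t_end = 6)
#' cmp[, c("scenario", "peak_G_b", "peak_I")]
#' }
compare_scenarios <- function(scenarios = c("healthy", "adipose", "liver",
                                            "muscle", "all"),
                              params = mf_params(), meal = mf_meal(),
                              t_end = 12, dt = 1 / 60, method = "lsoda",
                              rtol = 1e-8, atol = 1e-10,
                              recovery_tol = 0.01, ...) {
  sums <- list(); trajs <- list()
  for (sc in scenarios) {
    sens <- scenario_sensitivities(sc, ...)
    tr <- mf_simulate(params, sens, meal, t_end = t_end, dt = dt,
                      method = method, rtol = rtol, atol = atol)
    trajs[[sc]] <- tr
    sums[[sc]] <- summarise_trajectory(tr, recovery_tol = recovery_tol)
  }
  rows <- lapply(sums, function(s) data.frame(
    scenario = s$scenario,
    peak_G_b = s$peaks[["G_b"]], t_peak_G_b = s$t_peaks[["G_b"]],
    peak_I = s$peaks[["I"]], peak_T_b = s$peaks[["T_b"]],
    min_A_b = s$troughs[["A_b"]], peak_Y_L = s$peaks[["Y_L"]],
    peak_G_m = s$peaks[["G_m"]], peak_Y_m = s$peaks[["Y_m"]],
    net_hepatic_TAG_gain = s$net_hepatic_TAG_gain,
    flexibility_range = s$flexibility_range,
    total_oxidation = s$total_oxidation,
    peak_adipose_tag_clearance = s$peak_adipose_tag_clearance,
    n_glucose_peaks = s$n_glucose_peaks,
    recovery_time = s$recovery_time,
    recovered = s$recovered,
    row.names = NULL))
  out <- do.call(rbind, rows)
  attr(out, "summaries") <- sums
  attr(out, "trajectories") <- trajs
  out
}
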