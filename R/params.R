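## Parameter registry ---------------------------------------------------------
##
## Every rate constant of the kinetic model, on the dimensionless model scale
## (concentrations scaled by their healthy fasting values, time in hours).
## `source` records provenance: "literature" for constants whose dimensional
## counterpart is reported (the dimensionless stand-in is still a package
## default, because the per-variable concentration scales are not published),
## "default" for documented package placeholders, "zero" for processes that
## are deliberately switched off, "calibrated" for coefficients solved by
## `calibrate_to_unity_steady_state()`, and "derived" for meal fractions.

mf_registry <- function() {
  list(
    ## oxidation (muscle); solved by calibration so fasting uptake = oxidation
    M_G  = list(value = NA_real_, source = "calibrated",
                desc = "muscle glucose oxidation rate"),
    M_A  = list(value = NA_real_, source = "calibrated",
                desc = "muscle FFA oxidation rate"),
    ## muscle glycogen kinetics
    k_Y  = list(value = 2, source = "default",
                desc = "muscle glycogen synthesis rate (basal)"),
    k_YI = list(value = 0.5, source = "default",
                desc = "glycogen synthesis, insulin-stimulated weight"),
    k_YP = list(value = 1, source = "default",
                desc = "glycogen synthesis, AMP inhibition weight"),
    k_CP = list(value = NA_real_, source = "calibrated",
                desc = "glycogenolysis rate (AMP stimulated)"),
    k_CI = list(value = 0, source = "zero",
                desc = "glycogenolysis insulin inhibition (off)"),
    ## muscle uptake
    k_T  = list(value = 0.02, source = "literature",
                desc = "muscle TAG uptake rate (basal)"),
    k_G  = list(value = 0.0099, source = "literature",
                desc = "muscle glucose uptake rate (basal)"),
    k_GI = list(value = 100, source = "literature",
                desc = "muscle glucose uptake, insulin-stimulated weight"),
    k_A  = list(value = NA_real_, source = "calibrated",
                desc = "muscle FFA uptake rate"),
    ## whole-body sink
    S_G  = list(value = 0.01, source = "default",
                desc = "glucose consumption by the rest of the body"),
    ## AMP (P) kinetics; gamma_* are stoichiometric weights in the P balance
    mu       = list(value = NA_real_, source = "calibrated",
                    desc = "AMP production rate"),
    lambda_P = list(value = 4, source = "default",
                    desc = "AMP first-order degradation rate"),
    gamma_a  = list(value = 1, source = "default",
                    desc = "AMP consumed per unit FFA oxidation"),
    gamma_g  = list(value = 0.06, source = "default",
                    desc = "AMP consumed per unit glucose oxidation"),
    ## insulin kinetics
    lambda_I = list(value = NA_real_, source = "calibrated",
                    desc = "insulin degradation rate"),
    k_1  = list(value = 4, source = "literature",
                desc = "insulin production, erf model offset"),
    k_2  = list(value = 4, source = "literature",
                desc = "insulin production, erf model amplitude"),
    v    = list(value = 1.3, source = "default",
                desc = "erf model glucose threshold"),
    c    = list(value = 0.6, source = "default",
                desc = "erf model glucose width (> 0)"),
    k_IG = list(value = 3.2, source = "default",
                desc = "insulin production, linear glucose term"),
    k_I2 = list(value = 0.2, source = "default",
                desc = "insulin production, quadratic glucose term"),
    k_IA = list(value = 0.4, source = "default",
                desc = "insulin production, plasma FFA term"),
    ## basal outputs
    beta_A = list(value = 2.85, source = "literature",
                  desc = "adipose basal FFA output"),
    beta_T = list(value = 0.75, source = "literature",
                  desc = "hepatic basal TAG output"),
    beta_G = list(value = NA_real_, source = "calibrated",
                  desc = "hepatic basal glucose output"),
    ## insulin inhibition constants
    k_GL = list(value = 0.3, source = "literature",
                desc = "insulin inhibition of hepatic glucose output (I^2)"),
    k_TL = list(value = 1, source = "literature",
                desc = "insulin inhibition of hepatic TAG output"),
    k_AA = list(value = 1.98, source = "literature",
                desc = "insulin inhibition of adipose FFA output (I^2)"),
    ## adipose uptake
    k_TA = list(value = 0.1, source = "literature",
                desc = "adipose TAG uptake rate (basal)"),
    k_AI = list(value = 2, source = "literature",
                desc = "adipose TAG uptake, insulin-stimulated weight"),
    ## muscle TAG cycling
    k_X  = list(value = 1, source = "default",
                desc = "muscle TAG synthesis rate (basal)"),
    k_XI = list(value = 0, source = "zero",
                desc = "muscle TAG synthesis insulin stimulation (off)"),
    k_XP = list(value = 0, source = "zero",
                desc = "muscle TAG synthesis AMP inhibition (off)"),
    k_DP = list(value = NA_real_, source = "calibrated",
                desc = "muscle TAG lipolysis rate (AMP stimulated)"),
    k_DI = list(value = 0, source = "zero",
                desc = "muscle TAG lipolysis insulin inhibition (off)"),
    ## liver
    k_L   = list(value = 1.0286, source = "literature",
                 desc = "hepatic glucose uptake rate"),
    Y_max = list(value = 1.0007, source = "literature",
                 desc = "hepatic glycogen capacity (scaled)"),
    k_AL  = list(value = 0.015, source = "default",
                 desc = "hepatic lipogenesis (glucose to FFA) rate"),
    k_AS  = list(value = 1, source = "default",
                 desc = "insulin inhibition of hepatic FFA oxidation"),
    k_BL  = list(value = NA_real_, source = "calibrated",
                 desc = "plasma-to-liver FFA uptake rate"),
    k_LB  = list(value = 0.1, source = "default",
                 desc = "liver-to-plasma FFA release rate"),
    k_TH  = list(value = NA_real_, source = "calibrated",
                 desc = "hepatic TAG synthesis (esterification) rate"),
    S_L   = list(value = 0.1, source = "default",
                 desc = "hepatic FFA oxidation rate"),
    ## volume factors (left-hand-side multipliers); eta also absorbs the
    ## glycogen/glucose concentration-scale ratio of the liver stores
    alpha = list(value = 0.17, source = "literature",
                 desc = "plasma volume factor"),
    eta   = list(value = 2400, source = "default",
                 desc = "liver store capacitance factor"),
    ## saturation half-constants
    Y_0 = list(value = 2e-5, source = "default",
               desc = "glycogen saturation half-constant"),
    T_0 = list(value = NA_real_, source = "calibrated",
               desc = "hepatic TAG saturation half-constant"),
    ## meal
    B_G = list(value = 0.75, source = "default",
               desc = "feeding-to-plasma delay, glucose (h)"),
    B_T = list(value = 1.5, source = "default",
               desc = "feeding-to-plasma delay, TAG (h)"),
    theta_G = list(value = 550 / 700, source = "derived",
                   desc = "carbohydrate fraction of the meal"),
    theta_T = list(value = 150 / 700, source = "derived",
                   desc = "fat fraction of the meal"),
    F   = list(value = 5, source = "default",
               desc = "meal magnitude (dimensionless calorific content)"),
    ## retained registry entries that do not enter the kinetics (the meal
    ## source terms are fully specified by F, theta_*, B_*)
    k_FG = list(value = 0, source = "zero",
                desc = "unused: glucose-to-blood uptake rate"),
    k_FT = list(value = 0, source = "zero",
                desc = "unused: TAG-to-blood uptake rate")
  )
}

#' Model parameters
#'
#' Builds the full parameter set of the dimensionless model.  All values are
#' on the model scale (concentrations scaled by healthy fasting values, time
#' in hours).  Coefficients whose registry entry is marked `"calibrated"`
#' are solved by [calibrate_to_unity_steady_state()] so that the unity state
#' is the fasting reference state; all other entries are documented defaults
#' that can be overridden.
#'
#' @param overrides Named list of parameter values replacing registry
#'   defaults (e.g. `list(F = 4, k_GL = 0.5)`).  Unknown names are an error.
#' @param calibrate If `TRUE` (default) run the fasting-state calibration
#'   after applying overrides.
#' @param insulin_model `"quadratic"` (default, used by the numerical work)
#'   or `"erf"`; determines the insulin production function and therefore
#'   the calibrated insulin degradation rate.
#' @return An object of class `mf_params`: a named list of parameter values
#'   with attributes `provenance` (named character vector), `insulin_model`,
#'   and, after calibration, `calibrated = TRUE` and `fasting_drift` (the
#'   irreducible hepatic-glycogen drift of the fasting state, per hour).
#' @seealso [calibrate_to_unity_steady_state()], [mf_sensitivities()]
#' @export
#' @examples
#' p <- mf_params()
#' p$beta_G            # solved by calibration
#' attr(p, "fasting_drift")
mf_params <- function(overrides = list(), calibrate = TRUE,
                      insulin_model = c("quadratic", "erf")) {
  insulin_model <- match.arg(insulin_model)
  reg <- mf_registry()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(reg))
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (!is.numeric(val) || length(val) != 1L || is.na(val))
        stop("override for '", nm, "' must be a single numeric value",
             call. = FALSE)
      reg[[nm]]$value <- as.numeric(val)
      reg[[nm]]$source <- "overridden"
    }
  }
  p <- lapply(reg, `[[`, "value")
  attr(p, "provenance") <- vapply(reg, `[[`, character(1), "source")
  attr(p, "insulin_model") <- insulin_model
  attr(p, "calibrated") <- FALSE
  class(p) <- "mf_params"
  validate_params(p, allow_na = TRUE)
  if (calibrate) p <- calibrate_to_unity_steady_state(p) else p
}

validate_params <- function(p, allow_na = FALSE) {
  vals <- unlist(p, use.names = TRUE)
  if (!allow_na && anyNA(vals))
    stop("parameter set contains unresolved (NA) values; run ",
         "calibrate_to_unity_steady_state() first", call. = FALSE)
  fin <- vals[!is.na(vals)]
  if (any(!is.finite(fin)))
    stop("non-finite parameter value(s): ",
         paste(names(fin)[!is.finite(fin)], collapse = ", "), call. = FALSE)
  if (any(fin < 0))
    stop("negative parameter value(s): ",
         paste(names(fin)[fin < 0], collapse = ", "), call. = FALSE)
  for (nm in c("alpha", "eta", "Y_max", "c"))
    if (!is.na(p[[nm]]) && p[[nm]] <= 0)
      stop("parameter '", nm, "' must be > 0", call. = FALSE)
  if (p$theta_G + p$theta_T > 1 + 1e-12)
    stop("meal fractions theta_G + theta_T must not exceed 1", call. = FALSE)
  invisible(p)
}

#' @export
print.mf_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<mf_params> dimensionless model parameters (time unit: hours)\n")
  cat("  insulin model:", attr(x, "insulin_model"),
      if (isTRUE(attr(x, "calibrated"))) "| calibrated to unity fasting state"
      else "| NOT calibrated", "\n")
  df <- data.frame(value = signif(unlist(x), 6), source = prov)
  print(df, ...)
  if (!is.null(attr(x, "fasting_drift")))
    cat(sprintf("  fasting hepatic-glycogen drift: %.3e per hour\n",
                attr(x, "fasting_drift")))
  invisible(x)
}

## Sensitivity factors --------------------------------------------------------

#' Insulin sensitivity factors
#'
#' The eight multiplicative insulin-sensitivity factors.  A value of 1 means
#' normal sensitivity; values in (0, 1) model insulin resistance of the
#' corresponding pathway.
#'
#' @param ... Named overrides among `sigma_Y` (hepatic glucose uptake),
#'   `sigma_L` (hepatic glucose output suppression), `sigma_T` (hepatic TAG
#'   output suppression), `sigma_A`/`phi_A` (adipose FFA output),
#'   `sigma_AT`/`phi_AT` (adipose TAG uptake) and `sigma_G` (muscle glucose
#'   handling).
#' @return Named numeric vector of class `mf_sens`.
#' @export
#' @examples
#' mf_sensitivities()                 # healthy
#' mf_sensitivities(sigma_G = 0.2)    # insulin-resistant muscle
mf_sensitivities <- function(...) {
  s <- setNames(rep(1, length(mf_sens_names)), mf_sens_names)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("sensitivity overrides must be named", call. = FALSE)
    unknown <- setdiff(names(ov), mf_sens_names)
    if (length(unknown))
      stop("unknown sensitivity factor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(ov)) s[[nm]] <- as.numeric(ov[[nm]])
  }
  if (any(!is.finite(s)) || any(s <= 0) || any(s > 1))
    stop("sensitivity factors must lie in (0, 1]", call. = FALSE)
  class(s) <- "mf_sens"
  s
}

#' @export
print.mf_sens <- function(x, ...) {
  cat("<mf_sens> insulin sensitivity factors (1 = normal)\n")
  print(unclass(x), ...)
  invisible(x)
}

## Literature values for the resistant tissues.  sigma_G has two published
## readings (0.2 in the tabulated values, 0.15 in the muscle-scenario text);
## the table value is the default.
mf_ir_values <- function(sigma_G_text_value = FALSE,
                         strict_liver_text = FALSE) {
  list(
    adipose = c(sigma_A = 0.1, sigma_AT = 0.1, phi_A = 0.4, phi_AT = 0.4),
    liver = c(sigma_Y = if (strict_liver_text) 1 else 0.5,
              sigma_L = 0.06, sigma_T = 0.25),
    muscle = c(sigma_G = if (sigma_G_text_value) 0.15 else 0.2)
  )
}

#' Sensitivity factors for insulin-resistant tissues
#'
#' Maps a set of resistant tissues to the corresponding sensitivity factors.
#' A tissue that is listed resistant has exactly its own factors set to the
#' literature values; all other factors remain 1, so composition over
#' disjoint tissues is commutative.
#'
#' @param resistant_tissues Character vector, subset of
#'   `c("adipose", "liver", "muscle")` (empty = healthy).
#' @param sigma_G_text_value Use the text variant `sigma_G = 0.15` instead
#'   of the tabulated 0.2.
#' @param strict_liver_text Follow the liver-scenario text literally and
#'   keep `sigma_Y = 1` (the tabulated reading sets `sigma_Y = 0.5`).
#' @return `mf_sens` vector.
#' @export
#' @examples
#' apply_insulin_resistance(character())        # healthy
#' apply_insulin_resistance(c("adipose", "muscle"))
apply_insulin_resistance <- function(resistant_tissues = character(),
                                     sigma_G_text_value = FALSE,
                                     strict_liver_text = FALSE) {
  tissues <- unique(as.character(resistant_tissues))
  allowed <- c("adipose", "liver", "muscle")
  bad <- setdiff(tissues, allowed)
  if (length(bad))
    stop("unknown tissue name(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  s <- mf_sensitivities()
  vals <- mf_ir_values(sigma_G_text_value, strict_liver_text)
  for (ti in tissues) s[names(vals[[ti]])] <- vals[[ti]]
  class(s) <- "mf_sens"
  s
}

mf_scenario_names <- c("healthy", "adipose", "liver", "muscle",
                       "adipose+liver", "adipose+muscle", "liver+muscle",
                       "all")

#' Scenario name to sensitivity factors
#'
#' Accepted names: `"healthy"`, single tissues (`"adipose"`, `"liver"`,
#' `"muscle"`), pairwise combinations joined with `+`, and `"all"`.
#'
#' @inheritParams apply_insulin_resistance
#' @param name Scenario name.
#' @return `mf_sens` vector with attribute `scenario`.
#' @export
#' @examples
#' scenario_sensitivities("liver+muscle")
scenario_sensitivities <- function(name, sigma_G_text_value = FALSE,
                                   strict_liver_text = FALSE) {
  if (!is.character(name) || length(name) != 1L)
    stop("scenario name must be a single string", call. = FALSE)
  tissues <- scenario_tissues(name)
  s <- apply_insulin_resistance(tissues, sigma_G_text_value,
                                strict_liver_text)
  attr(s, "scenario") <- name
  s
}

scenario_tissues <- function(name) {
  if (name == "healthy") return(character())
  if (name == "all") return(c("adipose", "liver", "muscle"))
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  bad <- setdiff(parts, c("adipose", "liver", "muscle"))
  if (length(bad) || !length(parts))
    stop("unknown scenario '", name, "' (expected one of: ",
         paste(mf_scenario_names, collapse = ", "), ")", call. = FALSE)
  parts
}
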