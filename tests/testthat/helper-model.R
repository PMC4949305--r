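## Shared fixtures and independent oracles.

## memoised default calibrated parameters and scenario trajectories so the
## suite integrates each scenario only once
.cache <- new.env(parent = emptyenv())

cached_params <- function() {
  if (is.null(.cache$params)) .cache$params <- mf_params()
  .cache$params
}

cached_run <- function(scenario, t_end = 12, method = "lsoda") {
  key <- paste(scenario, t_end, method, sep = "|")
  if (is.null(.cache[[key]]))
    .cache[[key]] <- mf_simulate(cached_params(),
                                 scenario_sensitivities(scenario),
                                 t_end = t_end, method = method)
  .cache[[key]]
}

cached_summary <- function(scenario, ...) {
  key <- paste("sum", scenario, sep = "|")
  if (is.null(.cache[[key]]))
    .cache[[key]] <- summarise_trajectory(cached_run(scenario), ...)
  .cache[[key]]
}

## independent series oracle for the error function:
## erf(x) = 2/sqrt(pi) * sum_n (-1)^n x^(2n+1) / (n! (2n+1))
erf_series <- function(x, nmax = 40) {
  n <- 0:nmax
  2 / sqrt(pi) * sum((-1)^n * x^(2 * n + 1) / (factorial(n) * (2 * n + 1)))
}

## literal hand transcription of the thirteen printed balance equations,
## written independently of the package's flux assembly
rhs_direct <- function(y, t, p, s, model = "quadratic", meal = TRUE) {
  I <- y[[1]]; Gb <- y[[2]]; Tb <- y[[3]]; Ab <- y[[4]]; YL <- y[[5]]
  AL <- y[[6]]; TL <- y[[7]]; P <- y[[8]]; Gm <- y[[9]]; Ym <- y[[10]]
  Am <- y[[11]]; Tm <- y[[12]]
  f0 <- if (model == "quadratic") p$k_IG * Gb + p$k_I2 * Gb^2
    else p$k_1 + p$k_2 * (2 * pnorm(sqrt(2) * (Gb - p$v) / p$c) - 1)
  f1 <- YL / (p$Y_0 + YL)
  f2 <- (p$Y_max - YL) / (p$Y_0 + p$Y_max - YL)
  f3 <- TL / (p$T_0 + TL)
  FG <- if (meal) p$F * p$theta_G * t / p$B_G^2 * exp(-t^2 / (2 * p$B_G^2))
    else 0
  FT <- if (meal) p$F * p$theta_T * t / p$B_T^2 * exp(-t^2 / (2 * p$B_T^2))
    else 0
  c(I = f0 + p$k_IA * Ab - p$lambda_I * I,
    G_b = (p$beta_G / (1 + s[["sigma_L"]] * p$k_GL * I^2) * f1 -
             p$S_G * Gb -
             p$k_G * (1 + s[["sigma_G"]] * p$k_GI * I) * Gb -
             p$k_L * s[["sigma_Y"]] * I * Gb * f2 -
             p$k_AL * I * Gb + FG) / p$alpha,
    T_b = (p$beta_T / (1 + s[["sigma_T"]] * p$k_TL * I) * f3 -
             p$k_T * Tb -
             s[["phi_AT"]] * p$k_TA * (1 + s[["sigma_AT"]] * p$k_AI * I) * Tb +
             FT) / p$alpha,
    A_b = (s[["phi_A"]] * p$beta_A / (1 + s[["sigma_A"]] * p$k_AA * I^2) -
             p$k_A * Ab - p$k_BL * Ab + p$k_LB * AL) / p$alpha,
    Y_L = (p$k_L * s[["sigma_Y"]] * I * Gb * f2 -
             p$beta_G / (1 + s[["sigma_L"]] * p$k_GL * I^2) * f1) / p$eta,
    A_L = (p$k_AL * I * Gb - p$S_L * AL / (1 + p$k_AS * I) +
             p$k_BL * Ab - p$k_LB * AL - p$k_TH * I * AL) / p$eta,
    T_L = (p$k_TH * I * AL -
             p$beta_T / (1 + s[["sigma_T"]] * p$k_TL * I) * f3) / p$eta,
    P = p$mu - p$lambda_P * P - p$gamma_a * p$M_A * Am * P -
      s[["sigma_G"]] * p$gamma_g * p$M_G * P * I * Gm,
    G_m = p$k_G * (1 + s[["sigma_G"]] * p$k_GI * I) * Gb -
      s[["sigma_G"]] * p$M_G * P * I * Gm -
      p$k_Y * (1 + s[["sigma_G"]] * p$k_YI * I) / (1 + p$k_YP * P) * Gm +
      p$k_CP * P * Ym / (1 + s[["sigma_G"]] * p$k_CI * I),
    Y_m = p$k_Y * (1 + s[["sigma_G"]] * p$k_YI * I) / (1 + p$k_YP * P) * Gm -
      p$k_CP * P * Ym / (1 + s[["sigma_G"]] * p$k_CI * I),
    A_m = p$k_T * Tb + p$k_A * Ab - p$M_A * P * Am -
      p$k_X * (1 + p$k_XI * I) / (1 + p$k_XP * P) * Am +
      p$k_DP * P * Tm / (1 + p$k_DI * I),
    T_m = p$k_X * (1 + p$k_XI * I) / (1 + p$k_XP * P) * Am -
      p$k_DP * P * Tm / (1 + p$k_DI * I))
}

## random non-negative states (hepatic glycogen within its capacity)
random_states <- function(n, params, seed = 42) {
  set.seed(seed)
  m <- matrix(runif(12 * n, 0.05, 2), nrow = n,
              dimnames = list(NULL, c("I", "G_b", "T_b", "A_b", "Y_L",
                                      "A_L", "T_L", "P", "G_m", "Y_m",
                                      "A_m", "T_m")))
  m[, "Y_L"] <- runif(n, 0, params$Y_max)
  m
}

## per-equation volume factors (alpha: plasma, eta: liver, 1: rest)
volume_factors <- function(params) {
  c(I = 1, G_b = params$alpha, T_b = params$alpha, A_b = params$alpha,
    Y_L = params$eta, A_L = params$eta, T_L = params$eta,
    P = 1, G_m = 1, Y_m = 1, A_m = 1, T_m = 1)
}
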