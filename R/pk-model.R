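# One-compartment, first-order-absorption PK with oral dosing.
# Units are fixed internally: dose mg, volume L, time h, concentration ng/ml.
# The mg -> ng/ml conversion (1 mg/L = 1000 ng/ml) is applied once, here.

.MG_L_TO_NG_ML <- 1000

# Tolerance below which |ka - ke| is treated as the ka = ke degenerate case.
.KA_KE_TOL <- 1e-6

# Single-dose concentration contribution at time-since-dose dt >= 0,
# vectorized over all arguments. Bioavailability is folded into CL/F and V/F.
.conc_one_dose <- function(dose_mg, cl, v, ka, dt) {
  n <- length(dt)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  dose_mg <- rep_len(dose_mg, n)
  ke <- cl / v
  a <- dose_mg / v * .MG_L_TO_NG_ML
  degen <- abs(ka - ke) < .KA_KE_TOL
  out <- numeric(n)
  if (any(!degen)) {
    i <- !degen
    out[i] <- a[i] * ka[i] / (ka[i] - ke[i]) *
      (exp(-ke[i] * dt[i]) - exp(-ka[i] * dt[i]))
  }
  if (any(degen)) {
    i <- degen
    out[i] <- a[i] * ka[i] * dt[i] * exp(-ka[i] * dt[i])
  }
  out[dt < 0] <- 0
  out
}

#' Dosing regimen
#'
#' A regular oral dosing schedule: `n_doses` administrations of `dose_mg`
#' every `interval_h` hours starting at `first_dose_time_h`.
#'
#' @param dose_mg Amount per administration, mg (non-negative).
#' @param interval_h Inter-dose interval, h (positive).
#' @param n_doses Number of administrations (>= 1).
#' @param first_dose_time_h Time of the first dose, h.
#' @return An object of class `regimen`.
#' @examples
#' regimen(dose_mg = 21, interval_h = 24, n_doses = 14)
#' @export
regimen <- function(dose_mg, interval_h = 24, n_doses = 1, first_dose_time_h = 0) {
  stopifnot(dose_mg >= 0, interval_h > 0, n_doses >= 1)
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = as.integer(n_doses),
                 first_dose_time_h = first_dose_time_h),
            class = "regimen")
}

#' Concentration under a multiple-dose regimen
#'
#' Superposition solution of the one-compartment model with first-order
#' absorption: each administered dose contributes
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)} \left(e^{-k_e \Delta t} - e^{-k_a \Delta t}\right)}
#' with \eqn{k_e = CL/V} and bioavailability absorbed into the apparent
#' parameters. When \eqn{|k_a - k_e|} falls below an internal tolerance the
#' limiting form \eqn{D k_a \Delta t \, e^{-k_a \Delta t} / V} is used so the
#' expression never divides by a vanishing difference.
#'
#' @param ind Individual parameters: one row of [individual_params()] output,
#'   or any list/data frame with elements `cl`, `v`, `ka`.
#' @param reg A [regimen].
#' @param t Times at which to evaluate the concentration, h (vector).
#' @return Concentrations in ng/ml, same length as `t`.
#' @examples
#' ind <- individual_params(final_model_params(), weight = 70)
#' concentration(ind, regimen(21, 24, n_doses = 14), t = c(24, 48, 336))
#' @export
concentration <- function(ind, reg, t) {
  stopifnot(inherits(reg, "regimen"), all(t >= 0))
  cl <- ind$cl[[1]]; v <- ind$v[[1]]; ka <- ind$ka[[1]]
  stopifnot(cl > 0, v > 0, ka > 0)
  if (reg$dose_mg == 0) return(numeric(length(t)) )
  dose_times <- reg$first_dose_time_h + (seq_len(reg$n_doses) - 1) * reg$interval_h
  dt <- outer(t, dose_times, "-") # n_t x n_doses
  conc <- .conc_one_dose(dose_mg = reg$dose_mg, cl = cl, v = v, ka = ka,
                         dt = pmax(as.vector(dt), -1))
  conc[as.vector(dt) < 0] <- 0
  rowSums(matrix(conc, nrow = length(t)))
}

# Analytic steady-state pre-dose (trough) concentration for a regular
# regimen with interval tau; vectorized over cl, v, dose.
.ss_trough <- function(cl, v, ka, dose_mg, tau) {
  ke <- cl / v
  a <- dose_mg / v * .MG_L_TO_NG_ML
  a * ka / (ka - ke) *
    (exp(-ke * tau) / (1 - exp(-ke * tau)) - exp(-ka * tau) / (1 - exp(-ka * tau)))
}

# Analytic steady-state interval-average concentration (mass balance:
# dose rate divided by clearance); vectorized.
.ss_cavg <- function(cl, dose_mg, tau) {
  dose_mg * .MG_L_TO_NG_ML / (cl * tau)
}

#' Steady-state trough concentration
#'
#' Pre-dose concentration once accumulation is complete, from the analytic
#' multiple-dose accumulation formula (default) or by finite superposition
#' over `reg$n_doses` administrations (`method = "superposition"`, which
#' evaluates the concentration immediately before the last scheduled dose).
#'
#' @inheritParams concentration
#' @param method `"analytic"` (infinite-dose accumulation limit) or
#'   `"superposition"` (finite sum; agrees with the analytic value once
#'   `n_doses` spans ~10 elimination half-lives).
#' @return Steady-state trough concentration, ng/ml.
#' @examples
#' ind <- individual_params(final_model_params(), weight = 70)
#' steady_state_trough(ind, regimen(21, 24))
#' @export
steady_state_trough <- function(ind, reg, method = c("analytic", "superposition")) {
  method <- match.arg(method)
  stopifnot(inherits(reg, "regimen"))
  if (reg$dose_mg == 0) return(0)
  if (method == "analytic") {
    .ss_trough(ind$cl[[1]], ind$v[[1]], ind$ka[[1]], reg$dose_mg, reg$interval_h)
  } else {
    t_eval <- reg$first_dose_time_h + reg$n_doses * reg$interval_h
    concentration(ind, reg, t_eval)
  }
}

#' Apply the combined residual-error model
#'
#' Observed concentrations are generated from individual predictions as
#' \deqn{Q_i = P_i (1 + \epsilon_1) + \epsilon_2}
#' with \eqn{\epsilon_1 \sim N(0, \sigma^2_{prop})} and
#' \eqn{\epsilon_2 \sim N(0, \sigma^2_{add})}. Draws use R's current RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' Negative observed values can occur and are kept by default (they carry
#' information for estimation); set `clamp = TRUE` to truncate at zero for
#' reporting-style output.
#'
#' @param pred Individual predicted concentrations, ng/ml (non-negative).
#' @param pop A [pop_params] (only the sigma components are used).
#' @param clamp Truncate negative draws at zero? Default `FALSE`.
#' @return Observed concentrations, same length as `pred`.
#' @export
apply_residual_error <- function(pred, pop, clamp = FALSE) {
  stopifnot(inherits(pop, "pop_params"), all(pred >= 0))
  n <- length(pred)
  obs <- pred * (1 + stats::rnorm(n, 0, sqrt(pop$sigma2_prop))) +
    stats::rnorm(n, 0, sqrt(pop$sigma2_add))
  if (clamp) obs <- pmax(obs, 0)
  obs
}
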