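# Monte Carlo probability-of-target-attainment (PTA) engine: virtual
# patients at fixed weight, weight-proportional daily dosing once or twice
# daily, steady-state evaluation concentrations, and the 120-270 ng/ml
# therapeutic window.

#' Simulate steady-state concentrations for virtual patients
#'
#' Draws `n` random effects from the inter-individual distribution, builds
#' individual clearances and volumes at the given weight and fluoxetine
#' status, doses `dose_per_kg * weight` mg/day once daily (q24h) or split
#' evenly twice daily (q12h), and returns each virtual patient's
#' steady-state evaluation concentration from the analytic multiple-dose
#' accumulation formula.
#'
#' The evaluation metric defaults to the steady-state trough (pre-dose)
#' individual prediction; `metric = "cavg"` uses the interval-average
#' concentration (dose rate / clearance). Residual error is excluded by
#' default (`residual = FALSE`) so the metric reflects each patient's
#' underlying exposure; set `residual = TRUE` to superimpose one draw of
#' the combined error model.
#'
#' @param pop A [pop_params]; defaults to the final published model.
#' @param weight Body weight of the virtual patients, kg.
#' @param dose_per_kg Total daily dose, mg per kg per day.
#' @param regimen_type `"qd"` (once daily) or `"bid"` (twice daily, daily
#'   dose split evenly).
#' @param flu Fluoxetine co-medication flag, 0 or 1.
#' @param n Number of virtual patients.
#' @param metric `"trough"` or `"cavg"`.
#' @param residual Add residual error to the evaluation concentration?
#' @param seed Integer seed.
#' @return Numeric vector of `n` concentrations, ng/ml.
#' @examples
#' c70 <- simulate_virtual_patients(weight = 70, dose_per_kg = 0.3,
#'                                  regimen_type = "bid", n = 500, seed = 1)
#' pta(c70)
#' @export
simulate_virtual_patients <- function(pop = final_model_params(), weight,
                                      dose_per_kg,
                                      regimen_type = c("qd", "bid"),
                                      flu = 0, n = 1000,
                                      metric = c("trough", "cavg"),
                                      residual = FALSE, seed = NULL) {
  regimen_type <- match.arg(regimen_type)
  metric <- match.arg(metric)
  stopifnot(inherits(pop, "pop_params"), weight > 0, dose_per_kg >= 0, n >= 1,
            flu %in% c(0, 1))
  if (!is.null(seed)) set.seed(seed)
  eta <- stats::rnorm(n, 0, sqrt(pop$omega2_cl))
  ind <- individual_params(pop, weight = weight, flu = flu, eta_cl = eta)
  tau <- if (regimen_type == "qd") 24 else 12
  dose <- dose_per_kg * weight * tau / 24
  conc <- if (metric == "trough") {
    .ss_trough(ind$cl, ind$v, ind$ka, dose, tau)
  } else {
    .ss_cavg(ind$cl, dose, tau)
  }
  if (residual) conc <- apply_residual_error(conc, pop, clamp = TRUE)
  conc
}

#' Probability of target attainment
#'
#' Fraction of virtual patients attaining the therapeutic window
#' (default 120-270 ng/ml). With `attainment = "window"` (the default) a
#' patient attains when the evaluation concentration lies inside the
#' window; with `attainment = "floor"` a patient attains when the
#' concentration reaches at least the window's lower bound, i.e. sustained
#' exposure at or above the therapeutic floor.
#'
#' @param conc Evaluation concentrations, ng/ml (non-empty).
#' @param window Length-2 numeric, lower and upper bound in ng/ml.
#' @param attainment `"window"` or `"floor"`.
#' @return Probability in \[0, 1\].
#' @examples
#' pta(c(100, 150, 300))            # 1/3
#' pta(c(100, 150, 300), attainment = "floor")  # 2/3
#' @export
pta <- function(conc, window = c(120, 270),
                attainment = c("window", "floor")) {
  attainment <- match.arg(attainment)
  if (!length(conc)) stop("empty concentration vector")
  stopifnot(length(window) == 2, window[1] < window[2])
  if (attainment == "window") {
    mean(conc >= window[1] & conc <= window[2])
  } else {
    mean(conc >= window[1])
  }
}

#' PTA over the simulation design grid
#'
#' Runs the Monte Carlo engine over every combination of scenario
#' (fluoxetine status x regimen), dose and weight, and tabulates the
#' probability of target attainment.
#'
#' The default grid is the published simulation design: doses 0.1-0.8
#' mg/kg/day, weights 40/60/80/100/120 kg, 1000 virtual patients per cell,
#' four scenarios.
#'
#' @inheritParams simulate_virtual_patients
#' @param doses Dose grid, mg/kg/day.
#' @param weights Weight grid, kg.
#' @param flu Fluoxetine levels to simulate (subset of `c(0, 1)`).
#' @param regimen_types Regimens to simulate (subset of `c("qd", "bid")`).
#' @param window Therapeutic window, ng/ml.
#' @param attainment Attainment criterion, see [pta()].
#' @param seed Integer seed; each grid cell uses an independent substream
#'   derived from it.
#' @return A tibble: `flu`, `regimen`, `weight`, `dose_per_kg`, `pta`
#'   (in \[0, 1\]), `window_lo`, `window_hi`, `n`.
#' @examples
#' \donttest{
#' grid <- pta_grid(n = 200, seed = 1)
#' recommend_dose(grid)
#' }
#' @export
pta_grid <- function(pop = final_model_params(),
                     doses = seq(0.1, 0.8, by = 0.1),
                     weights = c(40, 60, 80, 100, 120),
                     flu = c(0, 1), regimen_types = c("qd", "bid"),
                     n = 1000, metric = c("trough", "cavg"),
                     residual = FALSE, window = c(120, 270),
                     attainment = c("window", "floor"), seed = NULL) {
  metric <- match.arg(metric)
  attainment <- match.arg(attainment)
  cells <- tidyr::expand_grid(flu = flu, regimen = regimen_types,
                              weight = weights,
                              dose_per_kg = round(doses, 10))
  cells$pta <- purrr::pmap_dbl(
    cells,
    function(flu, regimen, weight, dose_per_kg) {
      cell_seed <- if (is.null(seed)) NULL else
        .stage_seed(seed, paste(flu, regimen, weight, dose_per_kg))
      conc <- simulate_virtual_patients(pop, weight = weight,
                                        dose_per_kg = dose_per_kg,
                                        regimen_type = regimen, flu = flu,
                                        n = n, metric = metric,
                                        residual = residual,
                                        seed = cell_seed)
      pta(conc, window = window, attainment = attainment)
    })
  cells$window_lo <- window[1]; cells$window_hi <- window[2]; cells$n <- n
  cells
}

#' Weight-banded initial dose recommendation
#'
#' For every scenario and weight the grid dose with maximal PTA is picked
#' (ties resolved toward the lower dose), contiguous weights sharing the
#' same pick are merged into bands, and the achieved PTA range within each
#' band is reported.
#'
#' @param pta_table Output of [pta_grid()].
#' @return A tibble: `flu`, `regimen`, `weight_lo`, `weight_hi`,
#'   `dose_per_kg`, `pta_min`, `pta_max`.
#' @export
recommend_dose <- function(pta_table) {
  picks <- pta_table |>
    dplyr::group_by(.data$flu, .data$regimen, .data$weight) |>
    dplyr::arrange(.data$dose_per_kg, .by_group = TRUE) |>
    dplyr::slice_max(.data$pta, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$flu, .data$regimen, .data$weight)

  picks |>
    dplyr::group_by(.data$flu, .data$regimen) |>
    dplyr::mutate(band = cumsum(c(1, diff(match(.data$dose_per_kg,
                                                unique(.data$dose_per_kg))) != 0))) |>
    dplyr::group_by(.data$flu, .data$regimen, .data$band, .data$dose_per_kg) |>
    dplyr::summarise(weight_lo = min(.data$weight),
                     weight_hi = max(.data$weight),
                     pta_min = min(.data$pta), pta_max = max(.data$pta),
                     .groups = "drop") |>
    dplyr::select(!"band")
}

#' Locate the weight at which the optimal dose switches
#'
#' Bisects on body weight between two doses to find the boundary weight at
#' which their PTA curves cross, refining a band boundary that falls
#' between the simulation grid's weights.
#'
#' @inheritParams simulate_virtual_patients
#' @param dose_lo,dose_hi The two competing doses, mg/kg/day.
#' @param w_range Length-2 search interval for the boundary, kg; the lower
#'   dose must not already dominate at `w_range[1]`.
#' @param window,attainment See [pta()].
#' @param tol Weight tolerance, kg.
#' @return The crossing weight, kg (or a range endpoint when the ordering
#'   never switches inside the interval).
#' @export
locate_dose_boundary <- function(pop = final_model_params(), dose_lo, dose_hi,
                                 w_range, regimen_type = c("qd", "bid"),
                                 flu = 0, n = 1000,
                                 metric = c("trough", "cavg"),
                                 residual = FALSE, window = c(120, 270),
                                 attainment = c("window", "floor"),
                                 seed = NULL, tol = 0.5) {
  regimen_type <- match.arg(regimen_type)
  metric <- match.arg(metric)
  attainment <- match.arg(attainment)
  hi_wins <- function(w) {
    s1 <- if (is.null(seed)) NULL else .stage_seed(seed, paste("lo", round(w, 3)))
    s2 <- if (is.null(seed)) NULL else .stage_seed(seed, paste("hi", round(w, 3)))
    p_lo <- pta(simulate_virtual_patients(pop, w, dose_lo, regimen_type, flu,
                                          n, metric, residual, s1),
                window, attainment)
    p_hi <- pta(simulate_virtual_patients(pop, w, dose_hi, regimen_type, flu,
                                          n, metric, residual, s2),
                window, attainment)
    p_hi > p_lo
  }
  lo <- w_range[1]; hi <- w_range[2]
  f_lo <- hi_wins(lo); f_hi <- hi_wins(hi)
  if (f_lo == f_hi) return(if (f_lo) hi else lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (hi_wins(mid) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
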