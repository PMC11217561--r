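#' Specification of a synthetic sparse-TDM cohort
#'
#' Describes a study-like cohort of schizophrenia patients on oral
#' aripiprazole with sparse, trough-dominated therapeutic-drug-monitoring
#' sampling. Defaults emulate the reference cohort: 119 subjects, body
#' weight log-normal with median 67 kg truncated to 41-115 kg, 3/119 on
#' fluoxetine, label-typical maintenance doses, and 1-3 pre-dose samples
#' per subject at steady state with +/- 2 h timing jitter.
#'
#' @param n_subjects Number of subjects.
#' @param weight_median Median body weight, kg.
#' @param weight_cv Coefficient of variation of weight (log-normal scale).
#' @param weight_range Truncation bounds for weight, kg.
#' @param flu_prevalence Fraction of subjects on fluoxetine; the realized
#'   count is `round(flu_prevalence * n_subjects)`.
#' @param dose_levels Candidate total daily doses, mg/day.
#' @param bid_fraction Fraction of subjects dosed twice daily (the daily
#'   dose is split evenly); the rest are dosed once daily.
#' @param n_troughs Possible numbers of trough samples per subject (sampled
#'   uniformly).
#' @param trough_jitter_h Troughs are drawn within this many hours before a
#'   scheduled dose.
#' @param postdose_fraction Fraction of subjects contributing one extra
#'   random post-dose sample (drawn 1-12 h after a steady-state dose).
#' @param days Days of dosing before sampling (steady state for a ~34 h
#'   half-life drug).
#' @param dv_clamp Truncate negative observed concentrations at zero so the
#'   generated table satisfies the event-table invariants (default TRUE).
#' @param extra_covariates Number of inert (null) binary screening
#'   covariates to generate, named `X1`, `X2`, ... (default 0). Useful for
#'   exercising covariate-selection behaviour under the null.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 119, weight_median = 67,
                        weight_cv = 0.175, weight_range = c(41, 115),
                        flu_prevalence = 3 / 119,
                        dose_levels = c(10, 15, 20, 30),
                        bid_fraction = 0.2,
                        n_troughs = 1:3, trough_jitter_h = 2,
                        postdose_fraction = 0.2, days = 14,
                        dv_clamp = TRUE, extra_covariates = 0) {
  stopifnot(n_subjects >= 1, flu_prevalence >= 0, flu_prevalence <= 1,
            weight_range[1] < weight_range[2], all(dose_levels > 0),
            days >= 1)
  if (weight_median < weight_range[1] || weight_median > weight_range[2]) {
    stop("weight_median lies outside weight_range: truncation is infeasible")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), weight_median = weight_median,
         weight_cv = weight_cv, weight_range = weight_range,
         flu_prevalence = flu_prevalence, dose_levels = dose_levels,
         bid_fraction = bid_fraction, n_troughs = n_troughs,
         trough_jitter_h = trough_jitter_h,
         postdose_fraction = postdose_fraction, days = days,
         dv_clamp = dv_clamp, extra_covariates = as.integer(extra_covariates)),
    class = "cohort_spec"
  )
}

# Truncated log-normal weights by rejection; sdlog from the CV.
.draw_weights <- function(n, median, cv, range) {
  sdlog <- sqrt(log(1 + cv^2))
  out <- numeric(0)
  while (length(out) < n) {
    w <- stats::rlnorm(2 * n, meanlog = log(median), sdlog = sdlog)
    out <- c(out, w[w >= range[1] & w <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic TDM cohort from the population model
#'
#' Draws covariates and per-subject random effects, builds the dosing
#' history, computes true concentrations through the structural model, and
#' applies the combined residual-error model. The generating parameters and
#' each subject's realized random effect are attached as a ground-truth
#' manifest (see [ground_truth()]) so that estimation can be scored against
#' the simulation truth.
#'
#' @param spec A [cohort_spec].
#' @param pop Generating [pop_params] (default: the final published model).
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, pop, seed)`.
#' @return A validated event-table tibble with a `truth` attribute.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_subjects = 10), seed = 7)
#' dplyr::count(tab, EVID)
#' @export
generate_cohort <- function(spec, pop = final_model_params(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(pop, "pop_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects

  wt <- .draw_weights(n, spec$weight_median, spec$weight_cv, spec$weight_range)
  n_flu <- round(spec$flu_prevalence * n)
  flu <- integer(n)
  flu[sample.int(n, n_flu)] <- 1L
  eta <- stats::rnorm(n, 0, sqrt(pop$omega2_cl))
  ind <- individual_params(pop, weight = wt, flu = flu, eta_cl = eta)

  daily_dose <- sample(spec$dose_levels, n, replace = TRUE)
  bid <- stats::runif(n) < spec$bid_fraction
  interval <- ifelse(bid, 12, 24)
  n_doses <- as.integer(spec$days * 24 / interval)

  extras <- NULL
  if (spec$extra_covariates > 0) {
    extras <- matrix(stats::rbinom(n * spec$extra_covariates, 1, 0.2),
                     nrow = n,
                     dimnames = list(NULL, paste0("X", seq_len(spec$extra_covariates))))
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- regimen(dose_mg = daily_dose[i] / (24 / interval[i]),
                   interval_h = interval[i], n_doses = n_doses[i])
    dose_times <- (seq_len(n_doses[i]) - 1) * interval[i]
    k <- sample(spec$n_troughs, 1)
    # troughs drawn just before the last k scheduled doses (distinct days)
    trough_idx <- utils::tail(seq_len(n_doses[i]), k)
    obs_times <- dose_times[trough_idx] -
      stats::runif(k, 0, spec$trough_jitter_h)
    if (stats::runif(1) < spec$postdose_fraction) {
      base <- dose_times[utils::tail(trough_idx, 1)]
      obs_times <- c(obs_times, base + stats::runif(1, 1, 12))
    }
    obs_times <- sort(pmax(obs_times, 0))
    pred <- concentration(ind[i, ], reg, obs_times)
    dv <- apply_residual_error(pred, pop, clamp = spec$dv_clamp)
    sub <- tibble::tibble(
      ID = i,
      TIME = c(dose_times, obs_times),
      EVID = c(rep(1L, n_doses[i]), rep(0L, length(obs_times))),
      AMT = c(rep(reg$dose_mg, n_doses[i]), rep(NA_real_, length(obs_times))),
      DV = c(rep(NA_real_, n_doses[i]), dv),
      WT = wt[i], FLU = flu[i]
    )
    if (!is.null(extras)) {
      for (j in colnames(extras)) sub[[j]] <- extras[i, j]
    }
    rows[[i]] <- dplyr::arrange(sub, TIME, dplyr::desc(EVID))
  }
  out <- dplyr::bind_rows(rows)
  out <- validate_event_table(out)
  attr(out, "truth") <- list(
    pop = pop,
    subjects = tibble::tibble(ID = seq_len(n), WT = wt, FLU = flu,
                              eta = eta, cl = ind$cl, v = ind$v, ka = ind$ka,
                              daily_dose = daily_dose, interval_h = interval)
  )
  out
}

#' Ground-truth manifest of a generated cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return A list with `pop` (generating [pop_params]) and `subjects`
#'   (per-subject tibble of covariates, random effect, and realized CL/F,
#'   V/F, Ka).
#' @export
ground_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("no ground-truth manifest: was this cohort generated by generate_cohort()?")
  truth
}
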