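#' Goodness-of-fit table
#'
#' One row per observation with the quantities behind the standard popPK
#' diagnostic panels: population prediction (`pred`, random effect at 0),
#' individual prediction (`ipred`, at the empirical Bayes mode),
#' individual weighted residual `iwres = (obs - ipred) / sd(ipred)` with the
#' residual standard deviation from the combined error model evaluated at
#' `ipred`, and population weighted residual `wres` from the FOCE
#' linearization at eta = 0 (per-subject decorrelation by the linearized
#' marginal covariance).
#'
#' @param fit A [pk_fit()] result.
#' @return A tibble: `ID`, `time`, `obs`, `pred`, `ipred`, `iwres`,
#'   `abs_iwres`, `wres`. Rows where the residual standard deviation is
#'   zero carry `NA` residuals and are flagged in `degenerate`.
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_spec(n_subjects = 20), seed = 8)
#' fit <- pk_fit(tab)
#' gof(fit)
#' }
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  prep <- fit$prep
  th <- fit$th
  eta0 <- numeric(prep$S)
  pred <- .pred(prep, th, eta0)
  eta_hat <- fit$etas$eta[match(prep$ids, fit$etas$ID)]
  ipred <- .pred(prep, th, eta_hat)
  g_i <- th$s2p * ipred^2 + th$s2a
  degenerate <- g_i <= 0
  iwres <- ifelse(degenerate, NA_real_, (prep$y - ipred) / sqrt(g_i))

  # FOCE linearized marginal covariance at eta = 0, per subject
  d <- .ETA_FD
  Fg <- (.pred(prep, th, eta0 + d) - .pred(prep, th, eta0 - d)) / (2 * d)
  g0 <- th$s2p * pred^2 + th$s2a
  wres <- rep(NA_real_, prep$n_obs)
  for (s in seq_len(prep$S)) {
    idx <- which(prep$obs_subj == s)
    if (!length(idx)) next
    V <- diag(g0[idx], nrow = length(idx)) +
      th$omega2 * tcrossprod(Fg[idx])
    L <- try(chol(V), silent = TRUE)
    if (inherits(L, "try-error")) next
    wres[idx] <- backsolve(L, prep$y[idx] - pred[idx], transpose = TRUE)
  }

  obs_rows <- fit$data[fit$data$EVID == 0, ]
  tibble::tibble(
    ID = obs_rows$ID, time = obs_rows$TIME, obs = prep$y,
    pred = pred, ipred = ipred, iwres = iwres, abs_iwres = abs(iwres),
    wres = wres, degenerate = degenerate
  )
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicates of the study (same doses, times and
#' covariates) under the fitted model, prediction-corrects observed and
#' simulated concentrations within quantile-based time bins (each value is
#' scaled by the ratio of the bin median population prediction to the
#' observation's own population prediction), and summarizes the 2.5th, 50th
#' and 97.5th percentiles.
#'
#' @param fit A [pk_fit()] result.
#' @param n_sim Number of simulated replicates (>= 100; default 1000).
#' @param bins Number of quantile-based time bins (default 8).
#' @param seed Integer seed.
#' @return An object of class `vpc_result`: `bins` (per-bin tibble with
#'   observed and simulated percentiles and `n_obs`), `coverage` (fraction
#'   of prediction-corrected observations inside the simulated 2.5-97.5
#'   band of their bin), `n_sim`.
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_spec(n_subjects = 20), seed = 8)
#' fit <- pk_fit(tab)
#' vpc(fit, n_sim = 200, seed = 1)$coverage
#' }
#' @export
vpc <- function(fit, n_sim = 1000, bins = 8, seed = NULL) {
  stopifnot(inherits(fit, "pk_fit"), n_sim >= 100)
  if (!is.null(seed)) set.seed(seed)
  prep <- fit$prep
  th <- fit$th
  pred <- .pred(prep, th, numeric(prep$S))
  obs_rows <- fit$data[fit$data$EVID == 0, ]
  t_obs <- obs_rows$TIME

  # quantile bins on observation times; empty/duplicate edges collapse
  edges <- unique(stats::quantile(t_obs, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(t_obs, breaks = edges, include.lowest = TRUE)
  if (any(table(bin) == 0)) {
    warning("empty time bin(s) dropped")
    bin <- droplevels(bin)
  }
  pc_factor <- stats::ave(pred, bin, FUN = stats::median) / pred
  pc_obs <- prep$y * pc_factor

  sd_prop <- sqrt(th$s2p); sd_add <- sqrt(th$s2a)
  sims <- matrix(NA_real_, prep$n_obs, n_sim)
  for (r in seq_len(n_sim)) {
    eta <- stats::rnorm(prep$S, 0, sqrt(th$omega2))
    f <- .pred(prep, th, eta)
    dv <- f * (1 + stats::rnorm(prep$n_obs, 0, sd_prop)) +
      stats::rnorm(prep$n_obs, 0, sd_add)
    sims[, r] <- dv * pc_factor
  }

  probs <- c(0.025, 0.5, 0.975)
  lv <- levels(bin)
  bins_tbl <- dplyr::bind_rows(lapply(seq_along(lv), function(b) {
    idx <- which(bin == lv[b])
    qo <- stats::quantile(pc_obs[idx], probs)
    qs <- stats::quantile(as.vector(sims[idx, , drop = FALSE]), probs)
    tibble::tibble(bin = lv[b], t_mid = stats::median(t_obs[idx]),
                   n_obs = length(idx),
                   obs_lo = qo[1], obs_med = qo[2], obs_hi = qo[3],
                   sim_lo = qs[1], sim_med = qs[2], sim_hi = qs[3])
  }))

  lo <- bins_tbl$sim_lo[match(bin, bins_tbl$bin)]
  hi <- bins_tbl$sim_hi[match(bin, bins_tbl$bin)]
  coverage <- mean(pc_obs >= lo & pc_obs <= hi)

  structure(list(bins = bins_tbl, coverage = coverage, n_sim = n_sim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("pcVPC: %d simulated replicates, %.1f%% of observations inside the 2.5-97.5 band\n",
              x$n_sim, 100 * x$coverage))
  print(x$bins)
  invisible(x)
}
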