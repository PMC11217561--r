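#' Stepwise covariate selection by objective-function-value criteria
#'
#' Builds the covariate model in the conventional two-phase manner. In the
#' forward phase every remaining candidate is tested one at a time on top of
#' the current model and the candidate with the largest drop in objective
#' function value is added if the drop exceeds `forward` (default 6.63,
#' chi-square 1 df at p < 0.01). In the backward phase each included
#' covariate is removed in turn and is kept only if its removal raises the
#' objective by more than `backward` (default 10.8, p < 0.001).
#'
#' Candidate fits that fail to converge are skipped and recorded in the
#' audit trail; they are never treated as a zero change in objective.
#'
#' @param data An event table.
#' @param candidates List of [covariate_term()]s to screen.
#' @param forward Forward-inclusion threshold on the OFV decrease.
#' @param backward Backward-elimination threshold on the OFV increase.
#' @param ... Passed to [pk_fit()] (e.g. `method`, `ka_fixed`).
#' @return A list of class `stepwise_result`: `fit` (final [pk_fit()]),
#'   `selected` (list of retained terms), and `trace` (tibble auditing every
#'   tested step: phase, candidate, OFV, change, decision).
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_spec(n_subjects = 40), seed = 11)
#' sel <- stepwise_select(tab, list(flu_term()))
#' sel$trace
#' }
#' @export
stepwise_select <- function(data, candidates, forward = 6.63, backward = 10.8,
                            ...) {
  base <- pk_fit(data, covariates = list(), ...)
  current <- base
  included <- list()
  remaining <- candidates
  trace <- list()
  note <- function(phase, cand, ofv, delta, action, converged) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      phase = phase, candidate = cand, ofv = ofv, delta_ofv = delta,
      action = action, converged = converged)
  }
  note("base", NA_character_, base$ofv, NA_real_, "start", base$converged)

  if (!length(candidates)) {
    return(structure(list(fit = base, selected = list(),
                          trace = dplyr::bind_rows(trace)),
                     class = "stepwise_result"))
  }

  # forward inclusion
  repeat {
    if (!length(remaining)) break
    drops <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      cand <- remaining[[k]]
      f <- try(pk_fit(data, covariates = c(included, list(cand)),
                      init = current$estimates, ...), silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) {
        note("forward", cand$name, NA_real_, NA_real_, "skip_nonconverged", FALSE)
        next
      }
      drops[k] <- current$ofv - f$ofv
      fits[[k]] <- f
      note("forward", cand$name, f$ofv, drops[k], "test", TRUE)
    }
    if (all(is.na(drops)) || max(drops, na.rm = TRUE) <= forward) break
    best <- which.max(drops)
    note("forward", remaining[[best]]$name, fits[[best]]$ofv, drops[best],
         "add", TRUE)
    included <- c(included, remaining[best])
    current <- fits[[best]]
    remaining <- remaining[-best]
  }

  # backward elimination
  repeat {
    if (!length(included)) break
    rises <- rep(NA_real_, length(included))
    fits <- vector("list", length(included))
    for (k in seq_along(included)) {
      f <- try(pk_fit(data, covariates = included[-k],
                      init = current$estimates, ...), silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) {
        note("backward", included[[k]]$name, NA_real_, NA_real_,
             "skip_nonconverged", FALSE)
        next
      }
      rises[k] <- f$ofv - current$ofv
      fits[[k]] <- f
      note("backward", included[[k]]$name, f$ofv, rises[k], "test", TRUE)
    }
    removable <- which(!is.na(rises) & rises <= backward)
    if (!length(removable)) break
    worst <- removable[which.min(rises[removable])]
    note("backward", included[[worst]]$name, fits[[worst]]$ofv, rises[worst],
         "remove", TRUE)
    current <- fits[[worst]]
    included <- included[-worst]
  }

  structure(list(fit = current, selected = included,
                 trace = dplyr::bind_rows(trace)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  kept <- vapply(x$selected, function(cv) cv$name, character(1))
  cat("Stepwise covariate selection\n")
  cat("  retained:", if (length(kept)) paste(kept, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  final OFV %.3f\n", x$fit$ofv))
  invisible(x)
}

#' Nonparametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement (same number of subjects as the
#' original data), refits the model on each replicate, and summarizes each
#' parameter by the median and the 2.5th-97.5th percentile interval across
#' converged replicates. Bias is reported as
#' `(median - estimate) / estimate * 100%`.
#'
#' @param fit A [pk_fit()] result.
#' @param n_rep Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @return A list of class `pk_bootstrap`: `summary` (tibble with term,
#'   estimate, median, lower, upper, bias_pct), `n_success`, `n_rep`,
#'   `replicates` (tibble of per-replicate estimates).
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_spec(n_subjects = 25), seed = 2)
#' fit <- pk_fit(tab)
#' pk_bootstrap(fit, n_rep = 20, seed = 4)
#' }
#' @export
pk_bootstrap <- function(fit, n_rep = 1000, seed = NULL) {
  stopifnot(inherits(fit, "pk_fit"), n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  ids <- unique(data$ID)
  by_id <- split(data, data$ID)[as.character(ids)]
  reps <- vector("list", n_rep)
  for (b in seq_len(n_rep)) {
    take <- sample(seq_along(ids), length(ids), replace = TRUE)
    boot <- dplyr::bind_rows(lapply(seq_along(take), function(j) {
      d <- by_id[[take[j]]]
      d$ID <- j
      d
    }))
    f <- try(pk_fit(boot, covariates = fit$covariates, init = fit$estimates,
                    method = fit$method, ka_fixed = fit$estimates$ka),
             silent = TRUE)
    if (!inherits(f, "try-error") && f$converged) {
      reps[[b]] <- stats::setNames(.natural(f$th), f$term_names)
    }
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(ok) < 0.5) {
    stop("more than half of the bootstrap replicates failed to converge (",
         sum(!ok), "/", n_rep, ")")
  }
  mat <- do.call(rbind, reps[ok])
  est <- stats::setNames(.natural(fit$th), fit$term_names)
  summ <- tibble::tibble(
    term = colnames(mat),
    estimate = unname(est[colnames(mat)]),
    median = apply(mat, 2, stats::median),
    lower = apply(mat, 2, stats::quantile, 0.025),
    upper = apply(mat, 2, stats::quantile, 0.975)
  )
  summ$bias_pct <- (summ$median - summ$estimate) / summ$estimate * 100
  structure(list(summary = summ, n_success = sum(ok), n_rep = n_rep,
                 replicates = tibble::as_tibble(mat)),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged\n", x$n_success, x$n_rep))
  print(x$summary)
  invisible(x)
}

#' @rdname pk_bootstrap
#' @param x A `pk_bootstrap`.
#' @param ... Unused.
#' @method tidy pk_bootstrap
#' @export
tidy.pk_bootstrap <- function(x, ...) x$summary
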