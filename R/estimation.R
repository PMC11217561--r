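# FOCE-I estimation of the population model, with exact 1-D adaptive
# Gauss-Hermite quadrature as a selectable method. The model has a single
# random effect (log-normal eta on CL/F), which keeps both the conditional
# mode search and the quadrature cheap; all per-subject work is vectorized
# across subjects.

# Finite-difference step for derivatives with respect to eta.
.ETA_FD <- 1e-4

#' Covariate candidate for the clearance or volume model
#'
#' Describes one screening covariate and how it enters a structural
#' parameter: continuous covariates as a power term
#' \eqn{(x / x_{ref})^\theta} centred at the population median, categorical
#' 0/1 covariates as a linear fractional term \eqn{1 + \theta x}.
#'
#' @param name Column name in the event table.
#' @param param Parameter acted on: `"cl"` or `"v"`.
#' @param form `"linear"` (0/1 categorical) or `"power"` (continuous,
#'   strictly positive).
#' @param ref Reference value for the power form; default `NULL` uses the
#'   population median of the per-subject covariate values.
#' @return An object of class `cov_term`.
#' @examples
#' covariate_term("FLU", "cl", "linear")
#' @export
covariate_term <- function(name, param = c("cl", "v"),
                           form = c("linear", "power"), ref = NULL) {
  structure(list(name = name, param = match.arg(param),
                 form = match.arg(form), ref = ref),
            class = "cov_term")
}

#' Fluoxetine-on-clearance term of the final model
#'
#' @return The [covariate_term()] `1 + theta * FLU` acting on CL/F.
#' @export
flu_term <- function() covariate_term("FLU", "cl", "linear")

# --- internal fit-data preparation -----------------------------------------

.prep_fit_data <- function(data, covariates = list()) {
  data <- validate_event_table(data)
  ids <- unique(data$ID)
  sidx <- match(data$ID, ids)
  obs <- which(data$EVID == 0)
  dose <- which(data$EVID == 1)
  if (!length(obs)) stop("event table contains no observations")
  no_obs <- setdiff(seq_along(ids), unique(sidx[obs]))
  if (length(no_obs)) {
    warning(length(no_obs), " subject(s) without observations excluded from the likelihood")
  }

  # per-subject covariates (first row per subject)
  first <- match(ids, data$ID)
  wt_s <- data$WT[first]
  flu_s <- data$FLU[first]

  # (observation, prior dose) pairs within subject
  obs_by_s <- split(obs, sidx[obs])
  dose_by_s <- split(dose, sidx[dose])
  pair_obs <- integer(0); pair_dose <- integer(0)
  for (s in names(obs_by_s)) {
    o <- obs_by_s[[s]]; d <- dose_by_s[[s]]
    if (is.null(d)) next
    grid <- expand.grid(o = o, d = d)
    keep <- data$TIME[grid$d] <= data$TIME[grid$o]
    pair_obs <- c(pair_obs, grid$o[keep])
    pair_dose <- c(pair_dose, grid$d[keep])
  }
  obs_rank <- match(pair_obs, obs)

  cov_vals <- lapply(covariates, function(cv) {
    if (!cv$name %in% names(data)) {
      stop("covariate column not found in event table: ", cv$name)
    }
    x <- data[[cv$name]][first]
    if (cv$form == "power") {
      if (any(is.na(x)) ) stop("missing values in covariate ", cv$name)
      if (any(x <= 0)) stop("power-form covariate must be strictly positive: ", cv$name)
      ref <- if (is.null(cv$ref)) stats::median(x) else cv$ref
      list(x = x, ref = ref)
    } else {
      list(x = x, ref = NA_real_)
    }
  })

  list(
    ids = ids, S = length(ids),
    y = data$DV[obs], n_obs = length(obs),
    obs_subj = sidx[obs],
    pair_obs = obs_rank,                      # index into the obs vector
    pair_subj = sidx[pair_obs],
    pair_amt = data$AMT[pair_dose],
    pair_dt = data$TIME[pair_obs] - data$TIME[pair_dose],
    wt_s = wt_s, flu_s = flu_s,
    covariates = covariates, cov_vals = cov_vals,
    cache = new.env(parent = emptyenv())
  )
}

# Structural predictions for all observations given per-subject eta.
# th: list(theta_cl, theta_v, ka, cov_theta numeric vector)
.pred <- function(prep, th, eta) {
  cl_s <- th$theta_cl * (prep$wt_s / 70)^0.75
  v_s <- th$theta_v * (prep$wt_s / 70)
  if (length(prep$covariates)) {
    for (k in seq_along(prep$covariates)) {
      cv <- prep$covariates[[k]]
      xv <- prep$cov_vals[[k]]
      mult <- if (cv$form == "linear") 1 + th$cov_theta[k] * xv$x
              else (xv$x / xv$ref)^th$cov_theta[k]
      if (cv$param == "cl") cl_s <- cl_s * mult else v_s <- v_s * mult
    }
  }
  cl_s <- cl_s * exp(eta)
  contrib <- .conc_one_dose(prep$pair_amt, cl_s[prep$pair_subj],
                            v_s[prep$pair_subj], th$ka, prep$pair_dt)
  f <- numeric(prep$n_obs)
  acc <- rowsum(contrib, prep$pair_obs)
  f[as.integer(rownames(acc))] <- acc
  f
}

.subj_sum <- function(x, subj, S) {
  out <- numeric(S)
  acc <- rowsum(x, subj)
  out[as.integer(rownames(acc))] <- acc
  out
}

# Per-subject conditional objective (joint -2 log density without the
# eta-independent constant log(2 pi omega^2)):
#   q_s(eta) = sum_obs[(y-f)^2/g + log g] + eta^2/omega2
.inner_obj <- function(prep, th, eta) {
  f <- .pred(prep, th, eta)
  g <- th$s2p * f^2 + th$s2a
  contrib <- (prep$y - f)^2 / g + log(g)
  .subj_sum(contrib, prep$obs_subj, prep$S) + eta^2 / th$omega2
}

# Vectorized safeguarded Newton search for the conditional modes; returns
# eta_hat and the curvature (second derivative of q_s at the mode).
# Warm-starts from the modes of the previous call on the same prep (cached
# in prep$cache); the tight convergence tolerance makes the result
# independent of the starting point to well below the optimizer tolerance.
.inner_modes <- function(prep, th, max_iter = 30L) {
  eta <- if (!is.null(prep$cache) && !is.null(prep$cache$eta)) {
    prep$cache$eta
  } else {
    numeric(prep$S)
  }
  d <- .ETA_FD
  for (it in seq_len(max_iter)) {
    q0 <- .inner_obj(prep, th, eta)
    qp <- .inner_obj(prep, th, eta + d)
    qm <- .inner_obj(prep, th, eta - d)
    g1 <- (qp - qm) / (2 * d)
    g2 <- (qp - 2 * q0 + qm) / d^2
    g2 <- pmax(g2, 2 / th$omega2 * 1e-3)       # keep steps descent-directed
    step <- pmin(pmax(-g1 / g2, -1), 1)
    eta_new <- eta + step
    q_new <- .inner_obj(prep, th, eta_new)
    for (h in 1:6) {                           # vectorized backtracking
      worse <- q_new > q0 + 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      eta_new <- eta + step
      q_new <- .inner_obj(prep, th, eta_new)
    }
    eta <- eta + ifelse(q_new <= q0, step, 0)
    if (max(abs(step)) < 1e-8) break
  }
  if (!is.null(prep$cache)) prep$cache$eta <- eta
  qp <- .inner_obj(prep, th, eta + d)
  qm <- .inner_obj(prep, th, eta - d)
  q0 <- .inner_obj(prep, th, eta)
  list(eta = eta, curv = pmax((qp - 2 * q0 + qm) / d^2, 1e-8))
}

# FOCE-I objective: linearize around the conditional modes, with the
# residual variance evaluated at the conditional predictions (interaction).
.ofv_foce <- function(prep, th) {
  if (th$omega2 <= 0) {
    f <- .pred(prep, th, numeric(prep$S))
    g <- th$s2p * f^2 + th$s2a
    return(sum((prep$y - f)^2 / g + log(2 * pi * g)))
  }
  modes <- .inner_modes(prep, th)
  eta <- modes$eta
  d <- .ETA_FD
  f <- .pred(prep, th, eta)
  Fg <- (.pred(prep, th, eta + d) - .pred(prep, th, eta - d)) / (2 * d)
  g <- th$s2p * f^2 + th$s2a
  r <- prep$y - f + Fg * eta[prep$obs_subj]
  A <- .subj_sum(Fg^2 / g, prep$obs_subj, prep$S)
  B <- .subj_sum(Fg * r / g, prep$obs_subj, prep$S)
  C <- .subj_sum(r^2 / g, prep$obs_subj, prep$S)
  lg <- .subj_sum(log(2 * pi * g), prep$obs_subj, prep$S)
  den <- 1 + th$omega2 * A
  ofv <- sum(lg + log(den) + C - th$omega2 * B^2 / den)
  if (!is.finite(ofv)) ofv <- 1e10
  ofv
}

# Exact marginal -2 log-likelihood by adaptive Gauss-Hermite quadrature
# over the single eta dimension.
.ofv_agq <- function(prep, th, nodes = 21L) {
  if (th$omega2 <= 0) return(.ofv_foce(prep, th))
  gh <- pracma::gaussHermite(nodes)
  modes <- .inner_modes(prep, th)
  # curvature of -log joint density = q''/2
  sig <- sqrt(2 / modes$curv)
  loglik <- matrix(NA_real_, prep$S, nodes)
  for (k in seq_len(nodes)) {
    eta_k <- modes$eta + sqrt(2) * sig * gh$x[k]
    f <- .pred(prep, th, eta_k)
    g <- th$s2p * f^2 + th$s2a
    contrib <- (prep$y - f)^2 / g + log(2 * pi * g)
    q <- .subj_sum(contrib, prep$obs_subj, prep$S) +
      eta_k^2 / th$omega2 + log(2 * pi * th$omega2)
    loglik[, k] <- log(gh$w[k]) + gh$x[k]^2 + log(sqrt(2) * sig) - q / 2
  }
  m <- apply(loglik, 1, max)
  li <- m + log(rowSums(exp(loglik - m)))
  ofv <- -2 * sum(li)
  if (!is.finite(ofv)) ofv <- 1e10
  ofv
}

.th_from_pop <- function(pop, has_flu) {
  list(theta_cl = pop$theta_cl, theta_v = pop$theta_v, ka = pop$ka,
       omega2 = pop$omega2_cl, s2p = pop$sigma2_prop, s2a = pop$sigma2_add,
       cov_theta = if (has_flu) pop$theta_flu else numeric(0))
}

#' FOCE-I objective function value
#'
#' Returns the first-order-conditional-estimation-with-interaction
#' approximation to -2 log marginal likelihood of an event table under a
#' parameter set: per subject the conditional mode of the random effect is
#' located by a safeguarded Newton search, the model is linearized around
#' it, and the residual variance is evaluated at the conditional
#' predictions. Deterministic given `(pop, data)`.
#'
#' @param pop A [pop_params]; `theta_flu` is applied through the `FLU`
#'   column of the data.
#' @param data An event table.
#' @param method `"foce"` (default) or `"agq"` for exact adaptive 21-node
#'   Gauss-Hermite quadrature over the single random-effect dimension.
#' @param nodes Quadrature nodes for `method = "agq"`.
#' @return The objective function value (a scalar).
#' @examples
#' tab <- generate_cohort(cohort_spec(n_subjects = 12), seed = 3)
#' ofv_foce(final_model_params(), tab)
#' @export
ofv_foce <- function(pop, data, method = c("foce", "agq"), nodes = 21L) {
  method <- match.arg(method)
  stopifnot(inherits(pop, "pop_params"))
  prep <- .prep_fit_data(data, covariates = list(flu_term()))
  th <- .th_from_pop(pop, has_flu = TRUE)
  if (method == "foce") .ofv_foce(prep, th) else .ofv_agq(prep, th, nodes)
}

# --- parameter packing ------------------------------------------------------

.pack <- function(th, covariates) {
  ct <- vapply(seq_along(covariates), function(k) {
    if (covariates[[k]]$form == "linear") log(1 + th$cov_theta[k]) else th$cov_theta[k]
  }, numeric(1))
  c(log(th$theta_cl), log(th$theta_v), ct,
    log(th$omega2), log(th$s2p), log(th$s2a))
}

.unpack <- function(p, covariates, ka) {
  nc <- length(covariates)
  ct <- numeric(nc)
  if (nc) {
    raw <- p[2 + seq_len(nc)]
    for (k in seq_len(nc)) {
      ct[k] <- if (covariates[[k]]$form == "linear") exp(raw[k]) - 1 else raw[k]
    }
  }
  list(theta_cl = exp(p[1]), theta_v = exp(p[2]), ka = ka,
       omega2 = exp(p[2 + nc + 1]), s2p = exp(p[2 + nc + 2]),
       s2a = exp(p[2 + nc + 3]), cov_theta = ct)
}

.term_names <- function(covariates) {
  c("theta_cl", "theta_v",
    vapply(covariates, function(cv) paste0("theta_", cv$name), character(1)),
    "omega2_cl", "sigma2_prop", "sigma2_add")
}

.natural <- function(th) {
  c(th$theta_cl, th$theta_v, th$cov_theta, th$omega2, th$s2p, th$s2a)
}

# Naive-pooled starting values: clearance from steady-state mass balance on
# per-subject mean concentrations; volume from a typical-half-life prior
# (ke ~ 0.02/h); variances at conventional diffuse starts.
.init_values <- function(data, prep) {
  obs <- data[data$EVID == 0, ]
  dose <- data[data$EVID == 1, ]
  daily <- tapply(dose$AMT, dose$ID, function(a) sum(a) / (max(1, length(a))) ) # per-admin
  per_day <- tapply(dose$AMT, dose$ID, sum) /
    tapply(dose$TIME, dose$ID, function(t) max(diff(range(t)) / 24, 1))
  mean_dv <- tapply(pmax(obs$DV, 1), obs$ID, mean)
  ids <- intersect(names(per_day), names(mean_dv))
  wt <- prep$wt_s[match(ids, as.character(prep$ids))]
  cl_naive <- per_day[ids] * 1000 / (24 * mean_dv[ids]) / (wt / 70)^0.75
  cl0 <- stats::median(cl_naive, na.rm = TRUE)
  list(theta_cl = cl0, theta_v = cl0 / 0.02, omega2 = 0.1, s2p = 0.1,
       s2a = (0.15 * stats::median(obs$DV, na.rm = TRUE))^2)
}

#' Fit the population pharmacokinetic model
#'
#' Maximum-likelihood estimation (FOCE-I approximation by default) of the
#' one-compartment oral model with allometric weight scaling, a log-normal
#' random effect on CL/F, combined proportional + additive residual error,
#' and any number of covariate terms on CL/F or V/F. The absorption rate
#' constant is fixed (default 1.06/h). Positivity of the typical values and
#' variance components is enforced by log transformation; linear covariate
#' coefficients are constrained to `1 + theta > 0`.
#'
#' Standard errors come from the numerically differentiated Hessian of the
#' objective at the optimum and are reported as relative percentages.
#'
#' @param data An event table (see [validate_event_table()]).
#' @param covariates List of [covariate_term()]s to estimate; default the
#'   final-model structure (fluoxetine on clearance). Use `list()` for the
#'   weight-only base model.
#' @param init Optional [pop_params] giving starting values; default
#'   naive-pooled starts.
#' @param method `"foce"` or `"agq"`.
#' @param ka_fixed Fixed absorption rate constant, 1/h.
#' @param control Passed to [stats::nlminb()]; defaults request a relative
#'   objective tolerance of 1e-8.
#' @return An object of class `pk_fit` with estimates, relative standard
#'   errors, the objective function value, empirical Bayes random effects,
#'   and a convergence flag. Supports [tidy()], [glance()], [coef()].
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_spec(n_subjects = 30), seed = 5)
#' fit <- pk_fit(tab)
#' tidy(fit)
#' }
#' @export
pk_fit <- function(data, covariates = list(flu_term()), init = NULL,
                   method = c("foce", "agq"), ka_fixed = 1.06,
                   control = list(rel.tol = 1e-8, eval.max = 600, iter.max = 400)) {
  method <- match.arg(method)
  data <- validate_event_table(data)
  prep <- .prep_fit_data(data, covariates = covariates)
  objfun <- if (method == "foce") .ofv_foce else .ofv_agq

  if (is.null(init)) {
    iv <- .init_values(data, prep)
    th0 <- list(theta_cl = iv$theta_cl, theta_v = iv$theta_v, ka = ka_fixed,
                omega2 = iv$omega2, s2p = iv$s2p, s2a = iv$s2a,
                cov_theta = rep(0, length(covariates)))
  } else {
    stopifnot(inherits(init, "pop_params"))
    th0 <- .th_from_pop(init, has_flu = FALSE)
    th0$ka <- ka_fixed
    th0$cov_theta <- vapply(covariates, function(cv) {
      if (cv$name == "FLU" && cv$param == "cl") init$theta_flu else 0
    }, numeric(1))
    th0$omega2 <- max(th0$omega2, 1e-4)
    th0$s2p <- max(th0$s2p, 1e-6)
    th0$s2a <- max(th0$s2a, 1e-6)
  }

  p0 <- .pack(th0, covariates)
  obj_p <- function(p) {
    th <- .unpack(p, covariates, ka_fixed)
    v <- try(objfun(prep, th), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  opt <- stats::nlminb(p0, obj_p, control = control)
  th <- .unpack(opt$par, covariates, ka_fixed)
  converged <- opt$convergence == 0 && opt$objective < 1e10

  # standard errors on the natural scale
  nat <- .natural(th)
  nm <- .term_names(covariates)
  se_pct <- rep(NA_real_, length(nat)); names(se_pct) <- nm
  vcov_nat <- NULL
  hess <- try({
    obj_nat <- function(v) {
      nc <- length(covariates)
      thh <- list(theta_cl = v[1], theta_v = v[2], ka = ka_fixed,
                  omega2 = v[2 + nc + 1], s2p = v[2 + nc + 2],
                  s2a = v[2 + nc + 3], cov_theta = v[2 + seq_len(nc)])
      objfun(prep, thh)
    }
    stats::optimHess(nat, obj_nat,
                     control = list(ndeps = pmax(abs(nat) * 1e-4, 1e-7)))
  }, silent = TRUE)
  if (!inherits(hess, "try-error")) {
    vc <- try(2 * solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
        all(diag(vc) > 0)) {
      vcov_nat <- vc
      se_pct <- 100 * sqrt(diag(vc)) / abs(nat)
      names(se_pct) <- nm
    }
  }

  modes <- if (th$omega2 > 0) .inner_modes(prep, th)$eta else numeric(prep$S)
  flu_idx <- which(vapply(covariates, function(cv)
    cv$name == "FLU" && cv$param == "cl", logical(1)))
  est <- pop_params(theta_cl = th$theta_cl, theta_v = th$theta_v,
                    ka = ka_fixed,
                    theta_flu = if (length(flu_idx)) th$cov_theta[flu_idx[1]] else 0,
                    omega2_cl = th$omega2, sigma2_prop = th$s2p,
                    sigma2_add = th$s2a)

  structure(
    list(estimates = est, th = th, covariates = covariates,
         se_pct = se_pct, vcov = vcov_nat, ofv = opt$objective,
         etas = tibble::tibble(ID = prep$ids, eta = modes),
         converged = converged, n_subjects = prep$S, n_obs = prep$n_obs,
         method = method, data = data, prep = prep,
         term_names = nm),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): %d subjects, %d observations\n",
              toupper(x$method), x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f  converged: %s\n", x$ofv, x$converged))
  print(tidy(x))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  stats::setNames(.natural(object$th), object$term_names)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter estimates of a population PK fit
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`,
#'   `estimate`, `se_pct` (relative standard error, %).
#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(term = x$term_names,
                 estimate = unname(.natural(x$th)),
                 se_pct = unname(x$se_pct))
}

#' One-row summary of a population PK fit
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return A tibble with `ofv`, `converged`, `n_subjects`, `n_obs`, `method`.
#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, converged = x$converged,
                 n_subjects = x$n_subjects, n_obs = x$n_obs,
                 method = x$method)
}
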