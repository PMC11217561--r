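test_that("objective reduces to the weighted-least-squares form without random effects", {
  tab <- small_cohort(n = 10, seed = 6)
  s2a <- 40^2
  pop <- pop_params(theta_cl = 3.23, theta_v = 157, theta_flu = -0.286,
                    omega2_cl = 0, sigma2_prop = 0, sigma2_add = s2a)
  ofv <- ofv_foce(pop, tab)

  # independent computation: residuals against the eta = 0 prediction
  obs <- dplyr::filter(tab, EVID == 0)
  pred <- vapply(seq_len(nrow(obs)), function(i) {
    id <- obs$ID[i]
    doses <- dplyr::filter(tab, ID == id, EVID == 1)
    cov <- dplyr::filter(subject_covariates(tab), ID == id)
    ind <- individual_params(pop, cov$WT, cov$FLU)
    brute_conc(ind$cl, ind$v, ind$ka, doses$AMT[1], doses$TIME, obs$TIME[i])
  }, numeric(1))
  expect_equal(ofv, sum((obs$DV - pred)^2 / s2a + log(2 * pi * s2a)),
               tolerance = 1e-8)
})

test_that("FOCE-I agrees with adaptive Gauss-Hermite quadrature", {
  for (seed in 1:3) {
    tab <- small_cohort(n = 40, seed = seed)
    f_foce <- ofv_foce(table3, tab)
    f_agq <- ofv_foce(table3, tab, method = "agq")
    expect_lt(abs(f_foce - f_agq) / abs(f_agq), 0.01)
  }
})

test_that("the objective is invariant to subject relabeling and row order", {
  tab <- small_cohort(n = 25, seed = 9)
  ofv0 <- ofv_foce(table3, tab)

  # relabel subjects in reverse and re-sort
  relabeled <- tab
  relabeled$ID <- max(tab$ID) + 1 - tab$ID
  relabeled <- dplyr::arrange(relabeled, ID, TIME, dplyr::desc(EVID))
  expect_equal(ofv_foce(table3, relabeled), ofv0, tolerance = 1e-8)

  # shuffle whole subject blocks
  set.seed(1)
  shuffled <- dplyr::bind_rows(sample(split(tab, tab$ID)))
  expect_equal(ofv_foce(table3, shuffled), ofv0, tolerance = 1e-8)
})

test_that("fitting noise-free data from the truth returns the truth", {
  quiet <- pop_params(theta_cl = 3.23, theta_v = 157, theta_flu = -0.286,
                      omega2_cl = 1e-3, sigma2_prop = 1e-4, sigma2_add = 1)
  spec <- cohort_spec(n_subjects = 25, postdose_fraction = 0.5)
  tab <- generate_cohort(spec, quiet, seed = 14)
  fit <- pk_fit(tab, init = quiet)
  expect_equal(coef(fit)[["theta_cl"]], 3.23, tolerance = 0.01)
  expect_equal(coef(fit)[["theta_v"]], 157, tolerance = 0.03)
  expect_equal(length(fit$etas$eta), fit$n_subjects)
})

test_that("a full sparse cohort fit recovers the generating parameters", {
  tab <- small_cohort(n = 119, seed = 1)
  fit <- pk_fit(tab)
  expect_true(fit$converged)
  co <- coef(fit)
  expect_lt(abs(co[["theta_cl"]] - 3.23) / 3.23, 0.15)
  expect_lt(abs(co[["theta_v"]] - 157) / 157, 0.35)
  expect_lt(abs(co[["theta_FLU"]] - (-0.286)), 0.15)
  # relative standard errors are produced and finite for the fixed effects
  td <- tidy(fit)
  expect_true(all(is.finite(td$se_pct[td$term %in% c("theta_cl", "theta_v")])))
  gl <- glance(fit)
  expect_identical(gl$n_subjects, 119L)
  expect_true(is.finite(gl$ofv))
})

test_that("fits are deterministic and support broom-style accessors", {
  tab <- small_cohort(n = 20, seed = 5)
  f1 <- pk_fit(tab)
  f2 <- pk_fit(tab)
  expect_equal(f1$ofv, f2$ofv)
  expect_equal(coef(f1), coef(f2))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_named(tidy(f1), c("term", "estimate", "se_pct"))
})
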