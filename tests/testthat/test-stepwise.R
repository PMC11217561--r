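test_that("selection with no candidates returns the base model unchanged", {
  tab <- small_cohort(n = 15, seed = 3)
  sel <- stepwise_select(tab, list())
  base <- pk_fit(tab, covariates = list())
  expect_equal(sel$fit$ofv, base$ofv)
  expect_length(sel$selected, 0)
  expect_identical(sel$trace$action, "start")
})

test_that("forward inclusion detects the fluoxetine effect in most replicates", {
  # with only 3/119 exposed subjects detection is stochastic: the OFV drop
  # from adding the true effect exceeds 6.63 in well over half of replicates
  detected <- vapply(1:5, function(s) {
    tab <- generate_cohort(cohort_spec(), table3, seed = s)
    base <- pk_fit(tab, covariates = list())
    full <- pk_fit(tab, init = base$estimates)
    (base$ofv - full$ofv) > 6.63
  }, logical(1))
  expect_gte(sum(detected), 2)
})

test_that("a well-supported effect is retained and a null covariate is not", {
  # raise the exposure prevalence so the true effect survives the strict
  # backward threshold, and add an inert screening covariate
  spec <- cohort_spec(flu_prevalence = 0.3, extra_covariates = 1)
  tab <- generate_cohort(spec, table3, seed = 2)
  sel <- stepwise_select(tab, list(flu_term(),
                                   covariate_term("X1", "cl", "linear")))
  kept <- vapply(sel$selected, function(cv) cv$name, character(1))
  expect_true("FLU" %in% kept)
  expect_false("X1" %in% kept)
  # audit trail records every tested step with its OFV change
  tested <- dplyr::filter(sel$trace, action == "test")
  expect_true(all(c("FLU", "X1") %in% tested$candidate))
  expect_true(all(is.finite(tested$delta_ofv)))
})

test_that("the backward phase drops covariates below the elimination threshold", {
  tab <- small_cohort(n = 60, seed = 4)
  # force inclusion with a permissive forward threshold, then require the
  # strict backward criterion to prune a null covariate
  tab$X1 <- as.numeric(tab$ID %% 2 == 0)
  sel <- stepwise_select(tab, list(covariate_term("X1", "cl", "linear")),
                         forward = -1, backward = 10.8)
  kept <- vapply(sel$selected, function(cv) cv$name, character(1))
  expect_false("X1" %in% kept)
  expect_true(any(sel$trace$phase == "backward"))
})

test_that("bootstrap summarizes replicate estimates with coverage of the truth", {
  tab <- small_cohort(n = 40, seed = 6)
  fit <- pk_fit(tab, covariates = list())
  boot <- pk_bootstrap(fit, n_rep = 30, seed = 11)
  expect_equal(boot$n_success, 30)
  s <- boot$summary
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  # bias definition: (median - estimate)/estimate * 100%
  expect_equal(s$bias_pct, (s$median - s$estimate) / s$estimate * 100)
  # the interval for typical clearance covers the generating value
  cl <- s[s$term == "theta_cl", ]
  expect_gte(3.23, cl$lower)
  expect_lte(3.23, cl$upper)
  expect_identical(tidy(boot), boot$summary)
})

test_that("bootstrap resampling is reproducible under a seed", {
  tab <- small_cohort(n = 20, seed = 8)
  fit <- pk_fit(tab, covariates = list())
  b1 <- pk_bootstrap(fit, n_rep = 5, seed = 3)
  b2 <- pk_bootstrap(fit, n_rep = 5, seed = 3)
  expect_equal(b1$summary, b2$summary)
})
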