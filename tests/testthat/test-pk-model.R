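test_that("covariate model reproduces the final-model typical values", {
  ind <- individual_params(table3, weight = 70, flu = 0, eta_cl = 0)
  expect_equal(ind$cl, 3.23)
  expect_equal(ind$v, 157)
  expect_equal(ind$ka, 1.06)

  # fluoxetine multiplies clearance by 1 - 0.286 = 0.714
  flu <- individual_params(table3, weight = 70, flu = 1)
  expect_equal(flu$cl, 3.23 * 0.714)
  expect_equal(flu$v, 157)

  # allometric doubling of weight: CL x 2^0.75, V x 2
  big <- individual_params(table3, weight = 140)
  expect_equal(big$cl, 3.23 * 2^0.75)
  expect_equal(big$v, 314)
})

test_that("clearance ratio and allometric scaling hold at any weight and eta", {
  set.seed(42)
  for (i in 1:20) {
    w <- runif(1, 40, 120)
    eta <- rnorm(1, 0, 0.5)
    on <- individual_params(table3, w, flu = 1, eta_cl = eta)
    off <- individual_params(table3, w, flu = 0, eta_cl = eta)
    expect_equal(on$cl / off$cl, 1 + table3$theta_flu)
    ref <- individual_params(table3, 70, flu = 0, eta_cl = eta)
    expect_equal(off$cl / ref$cl, (w / 70)^0.75)
    expect_equal(off$v / ref$v, w / 70)
  }
})

test_that("parameter and covariate domain errors are raised", {
  expect_error(individual_params(table3, weight = -1), "weight")
  expect_error(individual_params(table3, weight = 70, flu = 2), "flu")
  expect_error(pop_params(theta_cl = 3, theta_v = 150, theta_flu = -1.2),
               "theta_flu")
  expect_error(pop_params(theta_cl = -3, theta_v = 150))
  expect_error(pop_params(theta_cl = 3, theta_v = 150, omega2_cl = -0.1),
               "non-negative")
})

test_that("superposition concentration matches a brute-force oracle", {
  ind <- individual_params(table3, weight = 55, flu = 0, eta_cl = 0.2)
  reg <- regimen(15, interval_h = 12, n_doses = 9)
  times <- c(0.5, 3, 11.9, 25, 60, 100.3)
  expected <- vapply(times, function(t)
    brute_conc(ind$cl, ind$v, ind$ka, 15, (0:8) * 12, t), numeric(1))
  expect_equal(concentration(ind, reg, times), expected, tolerance = 1e-12)
})

test_that("concentration obeys dose linearity, zero dose, and washout", {
  ind <- individual_params(table3, weight = 70)
  reg1 <- regimen(10, 24, 5)
  reg3 <- regimen(30, 24, 5)
  t <- c(1, 10, 50, 110)
  expect_equal(concentration(ind, reg3, t), 3 * concentration(ind, reg1, t))
  expect_equal(concentration(ind, regimen(0, 24, 5), t), rep(0, 4))
  # washout: essentially zero many half-lives after a single dose
  expect_lt(concentration(ind, regimen(20, 24, 1), 24 * 70), 1e-3)
  # multiple-dose superposition coincides with the single-dose solution
  # before the second dose is given
  t_pre <- c(1, 10, 23.9)
  expect_equal(concentration(ind, regimen(20, 24, 3), t_pre),
               concentration(ind, regimen(20, 24, 1), t_pre))
})

test_that("time-averaged steady-state concentration obeys mass balance", {
  # Css,avg = dose rate / CL: 21 mg/day at CL 3.23 L/h -> 270.9 ng/ml
  ind <- individual_params(table3, weight = 70)
  tt <- seq(0, 24, length.out = 4001)[-1] + 20 * 24
  cavg <- mean(concentration(ind, regimen(21, 24, 40), tt))
  expect_equal(cavg, 21e6 / 24 / 3.23 / 1000, tolerance = 0.002)
})

test_that("large ka approaches the IV-bolus one-compartment curve", {
  pop <- pop_params(theta_cl = 3.23, theta_v = 157, ka = 500)
  ind <- individual_params(pop, weight = 70)
  ke <- 3.23 / 157
  t <- c(2, 12, 24)
  iv <- 20 / 157 * 1000 * exp(-ke * t)
  expect_equal(concentration(ind, regimen(20, 24, 1), t), iv, tolerance = 0.01)
})

test_that("ka = ke degeneracy switches to the limiting form continuously", {
  ke <- 1.06 # choose cl, v so that ke equals ka exactly
  ind_degen <- list(cl = ke * 50, v = 50, ka = 1.06)
  ind_near <- list(cl = (ke + 1e-4) * 50, v = 50, ka = 1.06)
  t <- c(0.5, 1, 3, 8)
  c_degen <- concentration(ind_degen, regimen(10, 24, 1), t)
  c_near <- concentration(ind_near, regimen(10, 24, 1), t)
  expect_true(all(is.finite(c_degen)))
  expect_equal(c_degen, c_near, tolerance = 1e-3)
  # limiting form itself: D*ka*t/V * exp(-ka t)
  expect_equal(c_degen, 10 / 50 * 1000 * 1.06 * t * exp(-1.06 * t),
               tolerance = 1e-9)
})

test_that("analytic steady-state trough agrees with long superposition", {
  for (w in c(45, 70, 110)) {
    ind <- individual_params(table3, weight = w, eta_cl = 0.3)
    for (tau in c(12, 24)) {
      reg <- regimen(10, tau, n_doses = ceiling(24 / tau) * 120)
      expect_equal(steady_state_trough(ind, reg),
                   steady_state_trough(ind, reg, method = "superposition"),
                   tolerance = 1e-3)
    }
  }
})

test_that("steady-state trough is linear in dose and decreasing in clearance", {
  ind <- individual_params(table3, weight = 70)
  tr1 <- steady_state_trough(ind, regimen(10, 24))
  tr2 <- steady_state_trough(ind, regimen(20, 24))
  expect_equal(tr2, 2 * tr1)
  expect_equal(steady_state_trough(ind, regimen(0, 24)), 0)
  lo_cl <- individual_params(table3, weight = 70, eta_cl = -0.5)
  hi_cl <- individual_params(table3, weight = 70, eta_cl = 0.5)
  expect_gt(steady_state_trough(lo_cl, regimen(10, 24)),
            steady_state_trough(hi_cl, regimen(10, 24)))
})

test_that("residual error model is exact at zero variance and calibrated", {
  quiet <- pop_params(theta_cl = 3.23, theta_v = 157)
  pred <- c(0, 50, 200)
  expect_equal(apply_residual_error(pred, quiet), pred)

  set.seed(99)
  n <- 1e5
  # at pred = 0 only the additive term remains
  obs0 <- apply_residual_error(rep(0, n), table3)
  s2a <- table3$sigma2_add
  se_var <- s2a * sqrt(2 / (n - 1))
  expect_lt(abs(var(obs0) - s2a), 3 * se_var)
  # unbiasedness at a typical concentration
  obs <- apply_residual_error(rep(200, n), table3)
  sd_tot <- sqrt(200^2 * table3$sigma2_prop + s2a)
  expect_lt(abs(mean(obs) - 200), 3 * sd_tot / sqrt(n))
  # clamping truncates at zero
  expect_true(all(apply_residual_error(rep(1, n), table3, clamp = TRUE) >= 0))
})
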