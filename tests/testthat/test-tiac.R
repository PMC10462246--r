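test_that("trapezoidal TIAC evaluates head, trapezoid and physical-decay tail terms", {
  nuc <- nuclide_lp(0.1)
  tas <- time_activity_series("Liver", c(1, 2), c(0.8, 0.4))
  res <- tiac_trapezoid(tas, nuc)
  expect_equal(res$tiac_h, 0.8 + 0.6 + 4.0, tolerance = 1e-12)
  expect_equal(unname(res$components), c(0.8, 0.6, 4.0), tolerance = 1e-12)

  zero <- time_activity_series("Liver", c(1, 2), c(0, 0))
  expect_equal(tiac_trapezoid(zero, nuc)$tiac_h, 0)

  one <- time_activity_series("Liver", 1, 0.5)
  expect_error(tiac_trapezoid(one, nuc), class = "predose_validation_error")
})

test_that("trapezoid converges to the analytic integral at second order", {
  lp <- 0.05
  lb <- 0.2
  le <- lb + lp
  nuc <- nuclide_lp(lp)
  t1 <- 0.5
  tn <- 30
  exact <- t1 * exp(-le * t1) +                    # shared head assumption
    (exp(-le * t1) - exp(-le * tn)) / le +         # exact area over [T1, Tn]
    exp(-le * tn) / lp                             # shared tail assumption
  errs <- vapply(c(17, 33, 65, 129), function(n) {
    t <- seq(t1, tn, length.out = n)
    tas <- time_activity_series("R", t, exp(-le * t))
    abs(tiac_trapezoid(tas, nuc)$tiac_h - exact)
  }, 0)
  ratios <- errs[-length(errs)] / errs[-1]
  # halving the spacing cuts the error ~4x
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("noiseless multi-exponential data are recovered essentially exactly", {
  lp <- 0.05
  nuc <- nuclide_lp(lp)
  t <- plan_empirical(8, log(2) / 0.15)$times_h
  a <- 0.6 * exp(-0.15 * t) + 0.4 * exp(-0.06 * t)
  fit <- fit_exponentials(time_activity_series("Liver", t, a), nuc, components = 2)
  expect_true(fit$converged)
  expect_equal(fit$c, c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(fit$lambda_b, c(0.1, 0.01), tolerance = 1e-6)
  expect_lt(fit$wrss, 1e-20)
  expect_equal(tiac_from_fit(fit)$tiac_h, 0.6 / 0.15 + 0.4 / 0.06,
               tolerance = 1e-9)

  mono <- 0.7 * exp(-0.2 * t)
  f1 <- fit_exponentials(time_activity_series("K", t, mono), nuc, components = 1)
  expect_equal(f1$c, 0.7, tolerance = 1e-9)
  expect_equal(f1$lambda_b, 0.15, tolerance = 1e-7)
  expect_lt(f1$wrss, 1e-20)
})

test_that("auto model selection picks the generating number of components", {
  nuc <- nuclide_lp(0.05)
  t <- plan_empirical(9, 6)$times_h
  bi <- 0.6 * exp(-0.5 * t) + 0.4 * exp(-0.07 * t)
  fit <- fit_exponentials(time_activity_series("L", t, bi), nuc)
  expect_equal(fit$psi, 2L)
  mono <- 0.8 * exp(-0.25 * t)
  expect_equal(fit_exponentials(time_activity_series("L", t, mono), nuc)$psi, 1L)
})

test_that("degrees-of-freedom rule rejects over-parameterized fits", {
  nuc <- nuclide_lp(0.05)
  t4 <- c(1, 3, 8, 20)
  tas <- time_activity_series("L", t4, exp(-0.1 * t4))
  # bi-exponential: 4 parameters on 4 points leaves 0 degrees of freedom
  expect_error(fit_exponentials(tas, nuc, components = 2),
               "degrees-of-freedom", class = "predose_validation_error")
  expect_s3_class(fit_exponentials(tas, nuc, components = 1), "predose_fit")
  # with 5 points the bi-exponential becomes admissible
  t5 <- c(1, 3, 8, 20, 40)
  tas5 <- time_activity_series("L", t5, exp(-0.1 * t5))
  expect_s3_class(fit_exponentials(tas5, nuc, components = 2), "predose_fit")
  # two points cannot support any exponential model under "auto"
  t1 <- time_activity_series("L", c(1, 2), c(0.5, 0.4))
  expect_error(fit_exponentials(t1, nuc, components = "auto"), "degree")
})

test_that("analytic TIAC from fit parameters matches hand evaluation", {
  res <- tiac_from_fit(fake_fit(c(0.6, 0.4), c(0.1, 0.01), 0.05))
  expect_equal(res$tiac_h, 10.66667, tolerance = 1e-6)
  expect_equal(sum(res$components), res$tiac_h)

  # no biological elimination: TIAC is the radionuclide mean lifetime
  nuc6 <- radionuclide("t6", 6)
  res2 <- tiac_from_fit(fake_fit(1, 0, nuc6$lambda_p))
  expect_equal(res2$tiac_h, 1 / nuc6$lambda_p, tolerance = 1e-12)
  expect_equal(res2$tiac_h, 8.656171, tolerance = 1e-6)
  expect_equal(tiac_physical_decay(nuc6)$tiac_h, res2$tiac_h)

  expect_equal(tiac_from_fit(fake_fit(c(0, 0), c(0.1, 0.2), 0.05))$tiac_h, 0)
})

test_that("bladder closed form matches its analytic limits and validations", {
  fit <- fake_fit(1, 0.2, 0.1)
  # very long voiding interval: bladder retains everything it receives
  expect_equal(tiac_bladder(fit, 1, 1e6)$tiac_h, 1 / 0.1 - 1 / 0.3,
               tolerance = 1e-9)
  # continuous voiding removes the content immediately
  expect_lt(tiac_bladder(fit, 1, 1e-9)$tiac_h, 1e-8)
  expect_equal(tiac_bladder(fit, 0, 4)$tiac_h, 0)
  expect_error(tiac_bladder(fit, 1, -1), class = "predose_validation_error")
  expect_error(tiac_bladder(fit, 1.2, 4), class = "predose_validation_error")
  expect_error(tiac_bladder(fake_fit(1, 0, 0.1), 1, 4),
               "lambda_b = 0", class = "predose_validation_error")
})

test_that("bladder closed form agrees with the discrete fill/decay/void simulator", {
  set.seed(2024)
  n_grid <- 25
  lb <- exp(runif(n_grid, log(0.01), log(1)))
  lp <- exp(runif(n_grid, log(0.01), log(1)))
  fu <- runif(n_grid)
  tv <- runif(n_grid, 0.5, 12)
  for (i in seq_len(n_grid)) {
    cf <- tiac_bladder(fake_fit(1, lb[i], lp[i]), fu[i], tv[i])$tiac_h
    sim <- tiac_bladder_sim(fu[i], lb[i], lp[i], tv[i])
    if (cf > 0) expect_lt(abs(cf - sim) / cf, 1e-4)
  }
  # two-component clearance
  fit2 <- fake_fit(c(0.6, 0.4), c(0.5, 0.05), 0.08)
  cf2 <- tiac_bladder(fit2, c(0.5, 0.3), 3.5)$tiac_h
  sim2 <- tiac_bladder_sim(c(0.5, 0.3), c(0.5, 0.05), 0.08, 3.5)
  expect_lt(abs(cf2 - sim2) / cf2, 1e-4)
})

test_that("rest-of-body closure subtracts explicit sources and guards negativity", {
  tb <- tiac_result("Totalbody", 12, "exponential", lambda_p = 0.05)
  s1 <- tiac_result("Liver", 5, "exponential")
  s2 <- tiac_result("Kidneys", 4, "exponential")
  rob <- tiac_rest_of_body(tb, list(s1, s2))
  expect_equal(rob$tiac_h, 3)
  expect_equal(tiac_rest_of_body(tb, list())$tiac_h, 12)
  s3 <- tiac_result("Spleen", 4, "exponential")
  expect_error(tiac_rest_of_body(tb, list(s1, s2, s3)), "exceed",
               class = "predose_validation_error")
  expect_warning(rob0 <- tiac_rest_of_body(tb, list(s1, s2, s3), clamp = TRUE),
                 class = "predose_rob_clamped")
  expect_equal(rob0$tiac_h, 0)
  expect_error(tiac_rest_of_body(tb, list(s1, s1)), "more than once",
               class = "predose_validation_error")
})

test_that("TIACs never exceed the radionuclide mean lifetime on physical data", {
  set.seed(5)
  for (k in 1:20) {
    lp <- exp(runif(1, log(0.005), log(0.5)))
    nuc <- nuclide_lp(lp)
    lb <- exp(runif(2, log(0.01), log(1)))
    cc <- runif(2)
    cc <- cc / sum(cc) * runif(1)  # total a(0) <= 1
    t <- plan_empirical(6, log(2) / (mean(lb) + lp))$times_h
    a <- as.vector(exp(-outer(t, lb + lp)) %*% cc)
    tas <- time_activity_series("R", t, a)
    bound <- 1 / lp + 1e-9
    expect_lte(tiac_trapezoid(tas, nuc)$tiac_h, bound)
    expect_lte(tiac_from_fit(fit_exponentials(tas, nuc, components = 2))$tiac_h,
               bound)
  }
})

test_that("TIAC estimates scale linearly with the activity series", {
  nuc <- nuclide_lp(0.08)
  t <- plan_empirical(6, 5)$times_h
  a <- 0.5 * exp(-0.3 * t) + 0.2 * exp(-0.09 * t)
  tas1 <- time_activity_series("R", t, a)
  k <- 0.37
  tas2 <- time_activity_series("R", t, k * a)
  expect_equal(tiac_trapezoid(tas2, nuc)$tiac_h,
               k * tiac_trapezoid(tas1, nuc)$tiac_h, tolerance = 1e-12)
  f1 <- tiac_from_fit(fit_exponentials(tas1, nuc, components = 2))$tiac_h
  f2 <- tiac_from_fit(fit_exponentials(tas2, nuc, components = 2))$tiac_h
  expect_equal(f2, k * f1, tolerance = 1e-6)
})

test_that("fit and trapezoid TIACs agree on densely sampled exponential data", {
  lp <- 0.05
  nuc <- nuclide_lp(lp)
  t <- seq(0.25, 60, length.out = 120)
  a <- 0.8 * exp(-(0.15 + lp) * t)
  tas <- time_activity_series("R", t, a)
  trap <- tiac_trapezoid(tas, nuc)$tiac_h
  ana <- tiac_from_fit(fit_exponentials(tas, nuc, components = 1))$tiac_h
  expect_lt(abs(trap - ana) / ana, 0.01)
})
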