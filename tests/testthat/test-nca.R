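test_that("monoexponential curves reproduce the closed-form parameters", {
  # c(t) = 2 exp(-0.25 t), dose 30 mg: the analytic references are
  # kel = 0.25, AUCinf = c0/kel = 8, Vd = D/(AUC kel) = 15 l,
  # CL = 3.75 l/min, t1/2 = ln2/0.25, R15 = exp(-3.75)
  cur <- monoexp_curve(2, 0.25)
  pk <- pk_parameters(cur, dose = 30)
  expect_equal(pk$kel, 0.25, tolerance = 1e-6)
  expect_equal(pk$r_squared, 1, tolerance = 1e-9)
  expect_equal(pk$auc_inf, 8, tolerance = 0.005)
  expect_equal(pk$vd, 15, tolerance = 0.005)
  expect_equal(pk$cl, 3.75, tolerance = 0.005)
  expect_equal(pk$t_half, log(2) / 0.25, tolerance = 1e-6)
  expect_equal(pk$pdr, 25, tolerance = 1e-6)
  expect_equal(pk$r15, exp(-15 * 0.25), tolerance = 1e-4)
  expect_equal(pk$r20, exp(-20 * 0.25), tolerance = 1e-4)
  # invariant identities
  expect_equal(pk$t_half * pk$kel, log(2))
  expect_equal(pk$cl, pk$vd * pk$kel)
})

test_that("kel is invariant to a multiplicative rescaling of the curve", {
  cur <- monoexp_curve(2, 0.18)
  f1 <- fit_kel(cur$time, cur$conc)
  f2 <- fit_kel(cur$time, 7.3 * cur$conc)
  expect_equal(f1$kel, f2$kel)
  expect_equal(f2$c0, 7.3 * f1$c0, tolerance = 1e-9)
})

test_that("kel recovery is unbiased under multiplicative noise", {
  times <- seq(0, 20, by = 0.5)
  set.seed(123)
  kels <- replicate(100, {
    conc <- 2 * exp(-0.25 * times) * exp(rnorm(length(times), 0, 0.02))
    fit_kel(times, conc)$kel
  })
  expect_equal(mean(kels), 0.25, tolerance = 0.01 / 0.25)
  expect_lt(stats::sd(kels), 0.01)
})

test_that("AUC tail and trapezoid behave as specified", {
  # constant concentration over a single interval plus a negligible tail
  expect_equal(auc_infinity(c(0, 10), c(1, 1), kel = 1e6), 10,
               tolerance = 1e-5)
  # the tail term is exactly c_last / kel
  a1 <- auc_infinity(c(0, 1), c(1, 1), kel = 0.5)
  expect_equal(a1, 1 + 1 / 0.5)
  expect_error(auc_infinity(c(0, 1), c(1, 1), kel = 0), "positive")
})

test_that("dose linearity of the formulas: Vd and CL double, ratios unchanged", {
  cur <- monoexp_curve(2, 0.25)
  pk1 <- pk_parameters(cur, dose = 30)
  pk2 <- pk_parameters(cur, dose = 60)
  expect_equal(pk2$vd, 2 * pk1$vd)
  expect_equal(pk2$cl, 2 * pk1$cl)
  expect_equal(pk2$kel, pk1$kel)
  expect_equal(pk2$r15, pk1$r15)
})

test_that("R20 <= R15 for monotonically decaying curves", {
  for (kel in c(0.05, 0.15, 0.3)) {
    pk <- pk_parameters(monoexp_curve(3, kel), dose = 20)
    expect_lte(pk$r20, pk$r15)
  }
  tc <- healthy_bolus_tc()
  pk <- pk_parameters(tc)
  expect_lte(pk$r20, pk$r15)
})

test_that("simulated bolus decay is consistent with its fitted kel", {
  # the fitted elimination constant reproduces the simulated venous decay
  # over the fit window (the curve is effectively monoexponential there)
  tc <- healthy_bolus_tc()
  pk <- pk_parameters(tc)
  sel <- tc$time >= 5 & tc$time <= 15
  pred <- tc$cve_mg_per_l[tc$time == 5] *
    exp(-pk$kel * (tc$time[sel] - 5))
  expect_lt(max(abs(pred / tc$cve_mg_per_l[sel] - 1)), 0.02)
  expect_gt(pk$r_squared, 0.999)
})

test_that("degenerate fit windows are rejected", {
  cur <- monoexp_curve(2, 0.25, times = c(0, 1, 2, 30))
  expect_error(fit_kel(cur$time, cur$conc, window = c(5, 15)), "fewer than 3")
  expect_error(fit_kel(c(5, 8, 11, 14), c(1, 0.5, 0, -0.1)),
               "non-positive")
  expect_error(pk_parameters(monoexp_curve(2, 0.25), dose = -1), "dose")
})
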