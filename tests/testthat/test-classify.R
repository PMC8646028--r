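test_that("map fitting recovers coefficients from exact logarithmic data", {
  # scan generated from f = 0.312 ln(1.693 R15) + 0.861 exactly
  f <- seq(0.05, 0.9, by = 0.05)
  r15 <- exp((f - 0.861) / 0.312) / 1.693
  scan <- data.frame(value = f, r15 = r15)
  attr(scan, "parameter") <- "f_cirrhosis"
  class(scan) <- c("icg_scan", "data.frame")
  m <- fit_map_coefficients(scan)
  expect_equal(m$a, 0.312, tolerance = 1e-9)
  expect_equal(m$intercept, 0.312 * log(1.693) + 0.861, tolerance = 1e-9)
  # affine reparameterization identity: f = alpha ln(R15) + beta
  scan2 <- scan
  scan2$value <- 0.25 * log(scan$r15) + 0.95
  m2 <- fit_map_coefficients(scan2)
  expect_equal(m2$a, 0.25, tolerance = 1e-9)
  expect_equal(m2$intercept, 0.95, tolerance = 1e-9)
})

test_that("cirrhosis estimation evaluates and clamps the logarithmic map", {
  pub <- map_coefficients(0.312, 1.693, 0.861)
  expect_equal(estimate_fcirrhosis(0.10, pub),
               0.312 * log(1.693 * 0.10) + 0.861, tolerance = 1e-12)
  expect_equal(estimate_fcirrhosis(0.10, pub), 0.307, tolerance = 0.001)
  # R15 = 0.02 maps below zero and is clamped
  expect_equal(estimate_fcirrhosis(0.02, pub), 0)
  # the root of the map is exactly zero
  root <- exp(-0.861 / 0.312) / 1.693
  expect_equal(estimate_fcirrhosis(root, pub), 0, tolerance = 1e-12)
  expect_error(estimate_fcirrhosis(0, pub), "positive")
})

test_that("map round trip recovers the cirrhosis degree within 0.05", {
  m <- fitted_map()
  scan <- cirrhosis_scan()
  sel <- scan$value >= 0.1 & scan$value <= 0.8
  est <- estimate_fcirrhosis(scan$r15[sel], m)
  expect_lt(max(abs(est - scan$value[sel])), 0.05)
})

test_that("postoperative prediction is monotone in both risk factors", {
  surf <- surface_cache()
  rr <- seq(0, 0.9, by = 0.1)
  pred_rr <- predict_postop_r15(0.4, rr, surface = surf)
  expect_true(all(diff(pred_rr) > 0))
  f <- seq(0, 0.9, by = 0.1)
  pred_f <- predict_postop_r15(f, 0.3, surface = surf)
  expect_true(all(diff(pred_f) > 0))
  # no resection reproduces the cirrhosis-only prediction
  expect_equal(predict_postop_r15(0.4, 0, surface = surf),
               lookup_r15(surf, 0.4, 0))
})

test_that("surface interpolation matches exact simulation off the grid nodes", {
  surf <- surface_cache()
  exact <- predict_postop_r15(c(0.33, 0.62), c(0.18, 0.47), surface = NULL)
  interp <- predict_postop_r15(c(0.33, 0.62), c(0.18, 0.47), surface = surf)
  expect_equal(interp, exact, tolerance = 0.02)
})

test_that("feature definitions match their specification", {
  cohort <- data.frame(patient_id = c("a", "b"),
                       preop_r15 = c(0.20, 0.10),
                       resection_rate = c(0.5, 0.3),
                       survived = c(1L, 0L))
  pub <- map_coefficients(0.312, 1.693, 0.861)
  f1b <- build_features(cohort, "Data1B")
  expect_equal(unname(f1b$x[1, 1]), 0.20 * 0.5)
  expect_equal(ncol(build_features(cohort, "Data1A")$x), 1)
  expect_equal(ncol(build_features(cohort, "Data2")$x), 2)
  f2 <- build_features(cohort, "PBPK2", coeffs = pub)
  expect_equal(unname(f2$x[2, ]), c(0.307, 0.3), tolerance = 0.001)
  # non-survival is the positive class
  expect_equal(as.character(f1b$y), c("survivor", "nonsurvivor"))
  expect_error(build_features(cohort, "PBPK9"), "arg")
})

test_that("confusion-matrix metrics reproduce hand-computed values", {
  m <- metrics_from_confusion(tp = 3, fp = 1, fn = 1, tn = 9)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["npv"]), 0.9)
  expect_equal(unname(m["balanced_accuracy"]), 0.825)
  expect_equal(unname(m["f1"]), 0.75)
  expect_true(is.na(metrics_from_confusion(0, 0, 2, 5)["precision"]))
})

test_that("separable features are classified perfectly and deterministically", {
  set.seed(99)
  n <- 60
  x <- cbind(f = c(rnorm(n / 2, -4), rnorm(n / 2, 4)))
  y <- factor(rep(c("survivor", "nonsurvivor"), each = n / 2),
              levels = c("survivor", "nonsurvivor"))
  ft <- list(x = x, y = y, model = "toy")
  ev1 <- evaluate_classifier(ft, n_splits = 25, seed = 5)
  expect_equal(unname(ev1$full["roc_auc"]), 1)
  expect_equal(unname(ev1$full["balanced_accuracy"]), 1)
  expect_gt(unname(ev1$cv_mean["roc_auc"]), 0.99)
  ev2 <- evaluate_classifier(ft, n_splits = 25, seed = 5)
  expect_identical(ev1$cv, ev2$cv)
})

test_that("threshold AUC is invariant under monotone feature transforms", {
  set.seed(17)
  feature <- runif(80, 0, 0.6)
  death <- rbinom(80, 1, plogis((feature - 0.3) / 0.1))
  y <- factor(ifelse(death == 1, "nonsurvivor", "survivor"),
              levels = c("survivor", "nonsurvivor"))
  a1 <- icgpbpk:::roc_auc(y, feature)
  a2 <- icgpbpk:::roc_auc(y, log(feature + 1e-9))
  expect_equal(a1, a2)
  # and equals the independent rank-statistic oracle
  expect_equal(a1, rank_auc(feature, death == 1))
})

test_that("cutoff scan hits the degenerate extremes correctly", {
  feature <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  y <- factor(c("survivor", "survivor", "survivor", "nonsurvivor",
                "survivor", "nonsurvivor"),
              levels = c("survivor", "nonsurvivor"))
  cs <- cutoff_scan(feature, y, cutoffs = c(0, 0.35, 1), n_splits = 10,
                    seed = 3)
  expect_equal(cs$recall[cs$cutoff == 0], 1)
  expect_equal(cs$specificity[cs$cutoff == 0], 0)
  expect_equal(cs$recall[cs$cutoff == 1], 0)
  expect_equal(cs$recall[cs$cutoff == 0.35], 1)
  expect_equal(cs$specificity[cs$cutoff == 0.35], 0.75)
})
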