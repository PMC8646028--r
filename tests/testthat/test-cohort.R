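test_that("cohort generation is reproducible under the seed", {
  surf <- surface_cache()
  c1 <- generate_cohort(cohort_config(seed = 21), surf)
  c2 <- generate_cohort(cohort_config(seed = 21), surf)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(seed = 22), surf)
  expect_false(identical(c1$preop_r15, c3$preop_r15))
})

test_that("zero measurement noise reproduces the model R15 exactly", {
  surf <- surface_cache()
  coh <- generate_cohort(cohort_config(seed = 5, noise_cv = 0), surf)
  truth <- attr(coh, "truth")
  expect_equal(coh$preop_r15, truth$preop_r15_true)
  expect_equal(coh$preop_r15,
               lookup_r15(surf, truth$f_cirrhosis_true, 0))
})

test_that("generated cohorts have the expected composition and ranges", {
  surf <- surface_cache()
  fracs <- vapply(1:5, function(s) {
    coh <- generate_cohort(cohort_config(seed = s), surf)
    expect_true(all(coh$survived %in% c(0L, 1L)))
    expect_true(all(coh$preop_r15 > 0 & coh$preop_r15 < 1))
    expect_true(all(coh$resection_rate >= 0.05 &
                      coh$resection_rate <= 0.75))
    mean(1 - coh$survived)
  }, 0)
  # the non-survivor fraction tracks the 32/141 reference composition
  # (binomial SE at n = 141 is ~0.035 per cohort)
  expect_lt(abs(mean(fracs) - 32 / 141), 0.05)
})

test_that("cohort CSV and ground-truth sidecar round-trip losslessly", {
  surf <- surface_cache()
  coh <- generate_cohort(cohort_config(seed = 8, n = 40), surf)
  path <- withr::local_tempfile(fileext = ".csv")
  truth_path <- withr::local_tempfile(fileext = ".csv")
  export_cohort(coh, path, truth_path)
  back <- read_cohort(path)
  expect_equal(back$preop_r15, coh$preop_r15, tolerance = 1e-12)
  expect_equal(back$survived, coh$survived)
  truth <- utils::read.csv(truth_path)
  expect_equal(truth$f_cirrhosis_true,
               attr(coh, "truth")$f_cirrhosis_true, tolerance = 1e-12)
  # the sidecar is optional
  path2 <- withr::local_tempfile(fileext = ".csv")
  expect_silent(export_cohort(coh, path2))
})

test_that("the cirrhosis degree is recovered from noisy preoperative R15", {
  surf <- surface_cache()
  m <- fitted_map()
  coh <- generate_cohort(cohort_config(seed = 31), surf)
  truth <- attr(coh, "truth")
  est <- estimate_fcirrhosis(coh$preop_r15, m)
  expect_lt(mean(abs(est - truth$f_cirrhosis_true)), 0.08)
})

test_that("measurement noise erodes preop-only discrimination; the PBPK feature keeps its edge", {
  surf <- surface_cache()
  m <- fitted_map()
  auc_at_cv <- function(cv) {
    a1 <- 0; ap <- 0
    for (s in 1:6) {
      coh <- generate_cohort(cohort_config(seed = 100 + s, noise_cv = cv),
                             surf)
      death <- coh$survived == 0
      f_est <- estimate_fcirrhosis(coh$preop_r15, m)
      pbpk1 <- lookup_r15(surf, f_est, coh$resection_rate)
      a1 <- a1 + rank_auc(coh$preop_r15, death) / 6
      ap <- ap + rank_auc(pbpk1, death) / 6
    }
    c(data1a = a1, pbpk1 = ap)
  }
  res <- vapply(c(0.05, 0.6, 1.5), auc_at_cv, c(data1a = 0, pbpk1 = 0))
  # preoperative discrimination decays monotonically with noise
  expect_true(all(diff(res["data1a", ]) < 0))
  # the resection-rate information keeps the PBPK prediction ahead at
  # every noise level
  expect_true(all(res["pbpk1", ] > res["data1a", ]))
})

test_that("a deterministic death threshold is recovered by the cutoff scan", {
  surf <- surface_cache()
  set.seed(55)
  n <- 120
  f <- 0.9 * rbeta(n, 1.4, 1.55)
  rr <- runif(n, 0.05, 0.75)
  postop <- lookup_r15(surf, f, rr)
  y <- factor(ifelse(postop > 0.35, "nonsurvivor", "survivor"),
              levels = c("survivor", "nonsurvivor"))
  cs <- cutoff_scan(postop, y, cutoffs = seq(0.1, 0.6, by = 0.05),
                    n_splits = 20, seed = 9)
  best <- cs$cutoff[which.max(cs$balanced_accuracy)]
  expect_equal(best, 0.35, tolerance = 0.051)
})
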