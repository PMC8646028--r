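quick_block <- function(times = c(2, 5, 10), observed = NULL, sd = NULL,
                        n_subjects = 1, name = "block") {
  if (is.null(observed)) {
    # sample on the exact grid the objective simulates on, so residuals of
    # model-generated data vanish identically
    tc <- simulate_icg(times = sort(unique(c(0, times))))
    observed <- stats::approx(tc$time, tc$cve_mg_per_l, xout = times)$y
  }
  fit_block(name, times, observed, sd = sd, n_subjects = n_subjects)
}

test_that("objective vanishes exactly for model-generated data", {
  data <- fit_dataset(quick_block())
  p <- unlist(transporter_parameters()[icgpbpk:::FIT_PARAMETERS])
  expect_equal(fit_objective(p, data), 0)
})

test_that("objective implements the weighted per-block mean of squares", {
  data <- fit_dataset(quick_block())
  truth <- quick_block()$observed
  # single block: unit weights give mean squared residual times subjects
  shifted <- fit_block("s", c(2, 5, 10), truth + c(1, -2, 0.5))
  f1 <- fit_objective(unlist(transporter_parameters()[icgpbpk:::FIT_PARAMETERS]),
                      fit_dataset(shifted))
  expect_equal(f1, (1 + 4 + 0.25) / 3)
  # doubling the study weight doubles the contribution
  shifted2 <- fit_block("s", c(2, 5, 10), truth + c(1, -2, 0.5),
                        n_subjects = 2)
  f2 <- fit_objective(unlist(transporter_parameters()[icgpbpk:::FIT_PARAMETERS]),
                      fit_dataset(shifted2))
  expect_equal(f2, 2 * f1)
  # per-point errors enter as 1/sd weights
  fs <- fit_objective(unlist(transporter_parameters()[icgpbpk:::FIT_PARAMETERS]),
                      fit_dataset(fit_block("s", c(2, 5, 10),
                                            truth + c(1, -2, 0.5),
                                            sd = c(1, 2, 0.5))))
  expect_equal(fs, (1 + 1 + 1) / 3)
})

test_that("objective is invariant to block ordering", {
  b1 <- quick_block(name = "a")
  b2 <- fit_block("b", c(3, 6, 9), quick_block(c(3, 6, 9))$observed + 0.5,
                  n_subjects = 3)
  p <- unlist(transporter_parameters()[icgpbpk:::FIT_PARAMETERS])
  p["ICGIM_Vmax"] <- p[["ICGIM_Vmax"]] * 1.3
  expect_equal(fit_objective(p, fit_dataset(b1, b2)),
               fit_objective(p, fit_dataset(b2, b1)))
})

test_that("pathological parameters yield a non-finite cost with diagnostics", {
  data <- fit_dataset(quick_block())
  bad <- c(ICGIM_Vmax = -1)
  f <- fit_objective(bad, data)
  expect_true(is.infinite(f))
  expect_false(is.null(attr(f, "diagnostics")))
})

test_that("multi-start fitting is deterministic and returns the best start", {
  data <- fit_dataset(quick_block(seq(2, 14, by = 2)))
  f1 <- fit_transporters(data, n_starts = 2, seed = 11, maxiter = 8)
  f2 <- fit_transporters(data, n_starts = 2, seed = 11, maxiter = 8)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$starts, f2$starts)
  expect_true(all(f1$objective <= f1$starts$objective +
                    .Machine$double.eps))
  expect_error(fit_transporters(data, n_starts = 2), "seed")
})

test_that("a calibration dataset round-trips through CSV and YAML manifest", {
  dir <- withr::local_tempdir()
  blk <- quick_block(seq(2, 10, by = 2), n_subjects = 4)
  utils::write.csv(data.frame(time_min = blk$time, value = blk$observed,
                              sd = 0.05 * blk$observed),
                   file.path(dir, "block.csv"), row.names = FALSE)
  yaml::write_yaml(list(blocks = list(list(
    name = "bolus", csv = "block.csv", n_subjects = 4,
    protocol = list(list(kind = "bolus", amount = 0.5, per_kg = TRUE))
  ))), file.path(dir, "manifest.yaml"))
  data <- read_fit_dataset(file.path(dir, "manifest.yaml"))
  b <- data$blocks[[1]]
  expect_equal(b$observed, blk$observed)
  expect_equal(b$sd, 0.05 * blk$observed)
  expect_equal(b$n_subjects, 4)
  rp <- resolve_protocol(b$protocol, body_parameters())
  expect_equal(rp$total_mg, 37.5)
  expect_error(suppressWarnings(
    read_fit_dataset(file.path(dir, "missing.yaml"))))
})
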