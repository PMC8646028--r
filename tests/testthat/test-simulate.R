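test_that("zero dose yields identically zero observables", {
  tc <- simulate_icg(protocol = dosing_protocol(bolus_event(0)),
                     times = seq(0, 10, by = 0.5))
  expect_equal(max(abs(tc$cve_mg_per_l)), 0)
  expect_equal(max(tc$feces_mmole), 0)
  expect_true(all(is.na(tc$extraction_ratio)))
})

test_that("mass balance holds to integrator tolerance after a bolus", {
  tc <- healthy_bolus_tc()
  expect_lt(mass_conservation_error(tc), 1e-6)
})

test_that("states and observables stay non-negative; feces is non-decreasing", {
  tc <- healthy_bolus_tc()
  expect_true(all(tc$cve_mg_per_l >= 0))
  expect_true(all(tc$bile_mmole >= -1e-12))
  expect_true(all(diff(tc$feces_mmole) >= -1e-12))
  er <- tc$extraction_ratio[!is.na(tc$extraction_ratio) & tc$time > 1]
  expect_true(all(er >= 0 & er <= 1))
})

test_that("constant infusion reaches a steady state balancing elimination", {
  rate <- 0.25  # mg/min
  tc <- simulate_icg(protocol = infusion_protocol(rate, duration = 240),
                     times = seq(0, 240, by = 0.5))
  tail_idx <- tc$time >= 230
  cve <- tc$cve_mg_per_l[tail_idx]
  # plasma has plateaued
  expect_lt(diff(range(cve)) / mean(cve), 0.002)
  # hepatic elimination (flux into tissue + bile + feces) equals the
  # infusion rate at steady state
  elim_pool <- tc$liver_tissue_mmole + tc$bile_mmole + tc$feces_mmole
  elim_rate <- diff(elim_pool[tc$time %in% c(230, 240)]) / 10 * 774.96
  expect_equal(elim_rate, rate, tolerance = 0.02)
  # steady-state concentration is consistent with the NCA clearance of a
  # linear-regime bolus: c_ss = R / CL within 2%
  tc10 <- simulate_icg(protocol = dosing_protocol(bolus_event(10)),
                       times = seq(0, 60, by = 0.1))
  cl <- pk_parameters(tc10)$cl
  expect_equal(mean(cve), rate / cl, tolerance = 0.02)
})

test_that("halving the output step leaves the solution unchanged (< 0.1%)", {
  t_coarse <- seq(0, 30, by = 0.2)
  tc1 <- simulate_icg(times = t_coarse)
  tc2 <- simulate_icg(times = seq(0, 30, by = 0.1))
  c1 <- tc1$cve_mg_per_l[tc1$time %in% t_coarse]
  c2 <- tc2$cve_mg_per_l[tc2$time %in% t_coarse]
  expect_lt(max(abs(c1 - c2)) / max(c1), 1e-3)
})

test_that("venous concentrations scale nearly linearly at clinical doses", {
  times <- seq(0, 30, by = 0.1)
  tc10 <- simulate_icg(protocol = dosing_protocol(bolus_event(10)),
                       times = times)
  tc35 <- simulate_icg(protocol = dosing_protocol(bolus_event(35)),
                       times = times)
  sel <- tc10$time >= 1 & tc10$time <= 20
  ratio <- tc35$cve_mg_per_l[sel] / tc10$cve_mg_per_l[sel]
  expect_true(all(abs(ratio / 3.5 - 1) < 0.05))
  # far above the clinical range, uptake saturation breaks the scaling
  tc400 <- simulate_icg(protocol = dosing_protocol(bolus_event(400)),
                        times = times)
  ratio400 <- tc400$cve_mg_per_l[sel] / tc10$cve_mg_per_l[sel]
  expect_gt(max(abs(ratio400 / 40 - 1)), 0.15)
})

test_that("uncertainty envelope has the expected structure and exclusions", {
  env <- uncertainty_envelope(times = seq(0, 30, by = 0.5))
  # base + two runs per varied parameter
  expect_equal(env$n_runs, 2 * length(env$varied) + 1)
  expect_false(any(env$excluded %in% env$varied))
  expect_true(all(c("Mr_icg", "ti_icg", "dose") %in% env$excluded))
  # base trajectory lies within the pointwise envelope
  st <- env$stats$cve_mg_per_l
  expect_true(all(env$base$cve_mg_per_l >= st$min - 1e-12))
  expect_true(all(env$base$cve_mg_per_l <= st$max + 1e-12))
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
})

test_that("time-course CSV round-trips through the reproducibility header", {
  tc <- simulate_icg(times = seq(0, 10, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  first <- readLines(path, n = 1)
  expect_match(first, "^# ")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$time_min, tc$time)
  expect_equal(back$cve_mg_per_l, tc$cve_mg_per_l, tolerance = 1e-6)
  expect_equal(back$extraction_ratio[-1],
               tc$extraction_ratio[-1], tolerance = 1e-6)
})
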