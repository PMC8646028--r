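# shared fixtures, computed lazily and cached for the whole test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# standard cirrhosis scan: 0.5 mg/kg bolus, 75 kg reference, step 0.05
cirrhosis_scan <- function() {
  cached("cirrhosis_scan",
         run_scan("f_cirrhosis", seq(0, 0.9, by = 0.05)))
}

fitted_map <- function() {
  cached("fitted_map", fit_map_coefficients(cirrhosis_scan()))
}

# R15 surface over (f_cirrhosis x resection_rate), step 0.05 both axes
surface_cache <- function() {
  cached("surface", r15_surface())
}

healthy_bolus_tc <- function() {
  cached("healthy_bolus_tc",
         simulate_icg(times = seq(0, 60, by = 0.1)))
}

# independent rank-statistic (Mann-Whitney) AUC oracle
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exact monoexponential sampler: c(t) = c0 * exp(-kel * t) [mg/l]
monoexp_curve <- function(c0, kel, times = seq(0, 60, by = 0.05)) {
  list(time = times, conc = c0 * exp(-kel * times))
}
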