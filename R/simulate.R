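#' Simulate an ICG time course
#'
#' Integrates the whole-body ODE system for a given parameter set, scenario
#' and dosing protocol. Integration is restarted at every dosing
#' discontinuity (bolus start/end, infusion rate changes), so the input rate
#' is constant within each integration segment. A stiff-capable integrator
#' (\code{deSolve::lsoda}) is used with tight tolerances so that the mass
#' balance between administered dose, system content and cumulative feces
#' holds to the part-per-million level.
#'
#' @param params an \code{icg_parameters}.
#' @param scenario an \code{icg_scenario}.
#' @param protocol a \code{dosing_protocol} (resolved or not).
#' @param times strictly increasing output grid [min] starting at 0.
#'   Dosing breakpoints inside the horizon are added to the output grid so
#'   that concentration peaks at the end of an injection are captured.
#' @param rtol,atol relative and absolute integrator tolerances
#'   (defaults 1e-8 and 1e-10 mmole).
#' @return An object of class \code{icg_timecourse}: a data.frame with the
#'   time grid, plasma concentrations (venous, arterial, portal,
#'   hepatic-vein; mM and mg/l), liver tissue / bile / cumulative feces and
#'   administered amounts [mmole], the biliary excretion rate [mg/min] and
#'   the hepatic extraction ratio. Parameters, scenario, protocol and
#'   geometry are attached as attributes.
#' @export
#' @examples
#' tc <- simulate_icg(times = seq(0, 30, by = 0.1))
#' head(tc[tc$time >= 5, c("time", "cve_mg_per_l", "extraction_ratio")])
simulate_icg <- function(params = icg_parameters(),
                         scenario = scenario_parameters(),
                         protocol = standard_bolus(),
                         times = seq(0, 120, by = 0.1),
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(times) >= 2, times[1] == 0, all(diff(times) > 0))
  geometry <- derive_geometry(params$body, scenario)
  rp <- resolve_protocol(protocol, params$body)
  horizon <- max(times)
  bps <- protocol_breakpoints(rp)
  bps <- bps[bps > 0 & bps < horizon]
  out_times <- sort(unique(c(times, bps)))
  seg_bounds <- c(0, bps, horizon)

  y <- stats::setNames(rep(0, length(STATE_NAMES)), STATE_NAMES)
  rows <- vector("list", length(seg_bounds) - 1L)
  for (i in seq_len(length(seg_bounds) - 1L)) {
    lo <- seg_bounds[i]; hi <- seg_bounds[i + 1L]
    rate <- protocol_input_rate(rp, (lo + hi) / 2)
    seg_times <- unique(c(lo, out_times[out_times > lo & out_times < hi], hi))
    sol <- deSolve::lsoda(
      y, seg_times,
      func = function(t, state, p) {
        icg_rhs(t, state, params, geometry, function(tt) rate)
      },
      parms = NULL, rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf(paste0("integrator failure in segment [%.3f, %.3f] min ",
                          "(check parameters/protocol for pathologies)"),
                   lo, hi), call. = FALSE)
    }
    y <- sol[nrow(sol), -1L]
    rows[[i]] <- sol[if (i == 1L) TRUE else -1L, , drop = FALSE]
  }
  m <- do.call(rbind, rows)
  build_timecourse(m, params, scenario, rp, geometry)
}

build_timecourse <- function(m, params, scenario, protocol, geometry) {
  Mr <- params$body$Mr_icg
  Vp <- geometry$V_plasma
  time <- m[, 1L]
  amt <- m[, -1L, drop = FALSE]
  cve <- amt[, "ve"] / Vp[["ve"]]
  car <- amt[, "ar"] / Vp[["ar"]]
  cpo <- amt[, "po"] / Vp[["po"]]
  chv <- amt[, "hv"] / Vp[["hv"]]
  cli_t <- if (geometry$V_li_tissue > 0) {
    amt[, "li_tissue"] / geometry$V_li_tissue
  } else {
    rep(0, length(time))
  }
  v_bi <- biliary_excretion_rate_vec(cli_t, params$transporters,
                                     geometry$V_li_tissue)
  # flow-weighted mixed inflow (arterial + portal) for the extraction ratio
  c_in <- (geometry$Q_ha * car + geometry$Q_po * cpo) /
    (geometry$Q_ha + geometry$Q_po)
  er <- ifelse(c_in > 1e-12, (c_in - chv) / c_in, NA_real_)

  tc <- data.frame(
    time = time,
    cve_mM = cve, cve_mg_per_l = cve * Mr,
    car_mM = car, car_mg_per_l = car * Mr,
    cpo_mM = cpo, cpo_mg_per_l = cpo * Mr,
    chv_mM = chv, chv_mg_per_l = chv * Mr,
    liver_tissue_mmole = amt[, "li_tissue"],
    bile_mmole = amt[, "bile"],
    feces_mmole = amt[, "feces"],
    administered_mmole = amt[, "administered"],
    bile_excretion_mg_per_min = v_bi * Mr,
    extraction_ratio = er,
    row.names = NULL
  )
  attr(tc, "state") <- amt
  attr(tc, "params") <- params
  attr(tc, "scenario") <- scenario
  attr(tc, "protocol") <- protocol
  attr(tc, "geometry") <- geometry
  class(tc) <- c("icg_timecourse", "data.frame")
  tc
}

biliary_excretion_rate_vec <- function(c_liver_tissue, tp, v_liver_tissue) {
  tp$ICGLI2CA_Vmax * v_liver_tissue *
    c_liver_tissue / (tp$ICGLI2CA_Km + c_liver_tissue)
}

#' Relative mass-conservation error of a simulated time course
#'
#' @param tc an \code{icg_timecourse}.
#' @return Maximum over output times of
#'   \code{|administered - (system + feces)| / administered}, taken over
#'   times with a positive administered amount.
#' @export
mass_conservation_error <- function(tc) {
  amt <- attr(tc, "state")
  system_total <- rowSums(amt[, setdiff(colnames(amt), "administered"),
                              drop = FALSE])
  adm <- amt[, "administered"]
  ok <- adm > 0
  if (!any(ok)) return(0)
  max(abs(adm[ok] - system_total[ok]) / adm[ok])
}

# parameters varied in the uncertainty analysis: all physiological and
# kinetic constants except physical constants (Mr_icg), dosing (ti_icg and
# the dose amounts themselves), anthropometry not entering the equations
# (HEIGHT), and conservation-bound quantities (the lung receives the full
# cardiac output by construction)
uncertainty_varied_parameters <- function() {
  list(
    body = c("BW", "COBW", "HCT", "Fblood", "FVgi", "FVli", "FVlu", "FVve",
             "FVar", "FVbi", "FVpo", "FVhv", "FQgi", "FQh", "bil_plasma"),
    transporters = c("ICGIM_Vmax", "ICGIM_Km", "ki_bil", "ICGLI2CA_Vmax",
                     "ICGLI2CA_Km", "ICGLI2BI_k", "f_oatp1b3")
  )
}

#' Per-parameter uncertainty envelope
#'
#' Re-simulates the model with each eligible parameter individually scaled
#' by \code{1 - rel_change} and \code{1 + rel_change} (default +/-25%) and
#' summarizes the resulting bundle of trajectories pointwise (mean, SD,
#' minimum, maximum). Physical constants (\code{Mr_icg}), dosing
#' (\code{ti_icg} and dose amounts; the protocol is resolved against the
#' base body so per-kg doses do not change when \code{BW} is varied) and
#' conservation-bound flow fractions are excluded from variation.
#'
#' @inheritParams simulate_icg
#' @param rel_change relative perturbation (0.25 = +/-25%).
#' @param observables columns of the time course to summarize.
#' @return An object of class \code{icg_envelope}: list with the output
#'   \code{time} grid, per-observable pointwise statistics (\code{mean},
#'   \code{sd}, \code{min}, \code{max}), the base time course, the number
#'   of runs, and the varied/excluded parameter names.
#' @export
uncertainty_envelope <- function(params = icg_parameters(),
                                 scenario = scenario_parameters(),
                                 protocol = standard_bolus(),
                                 times = seq(0, 120, by = 0.1),
                                 rel_change = 0.25,
                                 observables = c("cve_mg_per_l",
                                                 "bile_excretion_mg_per_min",
                                                 "extraction_ratio")) {
  rp <- resolve_protocol(protocol, params$body)
  base <- simulate_icg(params, scenario, rp, times)
  varied <- uncertainty_varied_parameters()
  runs <- list(base)
  run_labels <- "base"
  for (group in names(varied)) {
    for (nm in varied[[group]]) {
      for (fac in c(1 - rel_change, 1 + rel_change)) {
        p2 <- params
        p2[[group]][[nm]] <- p2[[group]][[nm]] * fac
        tc <- tryCatch(
          simulate_icg(p2, scenario, rp, times),
          error = function(e) {
            stop(sprintf("uncertainty run failed for %s x%.2f: %s",
                         nm, fac, conditionMessage(e)), call. = FALSE)
          }
        )
        runs[[length(runs) + 1L]] <- tc
        run_labels <- c(run_labels, sprintf("%s_x%.2f", nm, fac))
      }
    }
  }
  time <- base$time
  stats_by_obs <- lapply(observables, function(obs) {
    mat <- vapply(runs, function(tc) tc[[obs]], numeric(length(time)))
    row_stat <- function(f) {
      apply(mat, 1L, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else f(v)
      })
    }
    data.frame(
      time = time,
      mean = row_stat(mean),
      sd = row_stat(stats::sd),
      min = row_stat(min),
      max = row_stat(max)
    )
  })
  names(stats_by_obs) <- observables
  structure(list(time = time, stats = stats_by_obs, base = base,
                 n_runs = length(runs), run_labels = run_labels,
                 varied = unlist(varied, use.names = FALSE),
                 excluded = c("Mr_icg", "ti_icg", "HEIGHT", "dose"),
                 rel_change = rel_change),
            class = "icg_envelope")
}

#' @export
print.icg_envelope <- function(x, ...) {
  cat(sprintf("ICG uncertainty envelope: %d runs (+/-%.0f%% on %d parameters)\n",
              x$n_runs, 100 * x$rel_change, length(x$varied)))
  cat("  excluded from variation:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
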