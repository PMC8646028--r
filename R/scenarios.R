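#' Cirrhosis degrees of the Child-Turcotte-Pugh classes
#'
#' Composite cirrhosis degrees assigned to the CTP severity classes, as
#' obtained by mapping clinical pharmacokinetic parameters of the CTP
#' groups onto the systematic model scan: control 0.0, mild (CTP-A) 0.41,
#' moderate (CTP-B) 0.70, severe (CTP-C) 0.82.
#'
#' @return Named numeric vector of \code{f_cirrhosis} values, increasing
#'   with severity.
#' @export
#' @examples
#' ctp_mapping()[["moderate"]]
ctp_mapping <- function() {
  c(control = 0.0, mild = 0.41, moderate = 0.70, severe = 0.82)
}

scan_parameter_range <- function(parameter) {
  switch(parameter,
         f_cirrhosis = ,
         f_shunts = ,
         f_tissue_loss = c(0, 1 - 1e-9),
         resection_rate = c(0, 0.9),
         f_bloodflow = c(1e-9, Inf),
         dose = c(1e-9, Inf),
         stop("unknown scan parameter: ", parameter, call. = FALSE))
}

#' Parameter scan of ICG pharmacokinetic parameters
#'
#' Simulates a standard bolus for every value of a scenario parameter and
#' computes the non-compartmental parameters per point. Setting
#' \code{f_cirrhosis} varies intrahepatic shunting and functional tissue
#' loss in lockstep; \code{dose} varies the administered bolus [mg] with
#' the scenario held fixed.
#'
#' @param parameter one of \code{"f_cirrhosis"}, \code{"f_shunts"},
#'   \code{"f_tissue_loss"}, \code{"resection_rate"}, \code{"f_bloodflow"},
#'   \code{"dose"}.
#' @param grid strictly increasing values within the parameter's admissible
#'   range.
#' @param params an \code{icg_parameters}.
#' @param base_scenario scenario holding the non-scanned parameters.
#' @param protocol dosing protocol (ignored for a dose scan, where an
#'   absolute bolus of each grid value is administered).
#' @param times simulation grid [min]; the default 0--60 min at 0.1 min
#'   covers the monoexponential elimination phase used by the
#'   non-compartmental analysis.
#' @param window kel fit window [min].
#' @return An object of class \code{icg_scan}: data.frame with the scanned
#'   \code{value} and one column per pharmacokinetic parameter.
#' @export
#' @examples
#' \donttest{
#' scan <- run_scan("f_cirrhosis", seq(0, 0.9, by = 0.3))
#' scan[, c("value", "r15", "cl")]
#' }
run_scan <- function(parameter, grid,
                     params = icg_parameters(),
                     base_scenario = scenario_parameters(),
                     protocol = standard_bolus(),
                     times = seq(0, 60, by = 0.1),
                     window = c(5, 15)) {
  stopifnot(length(grid) >= 1, all(diff(grid) > 0))
  rng <- scan_parameter_range(parameter)
  if (any(grid < rng[1] | grid > rng[2])) {
    stop(sprintf("grid values outside admissible range of %s", parameter),
         call. = FALSE)
  }
  rows <- lapply(grid, function(v) {
    if (parameter == "dose") {
      sc <- base_scenario
      prot <- dosing_protocol(bolus_event(v))
    } else {
      sc_args <- unclass(base_scenario)
      if (parameter == "f_cirrhosis") {
        sc_args$f_shunts <- v
        sc_args$f_tissue_loss <- v
      } else {
        sc_args[[parameter]] <- v
      }
      sc <- do.call(scenario_parameters, sc_args)
      prot <- protocol
    }
    tc <- simulate_icg(params, sc, prot, times)
    cbind(value = v, as.data.frame(pk_parameters(tc, window = window)))
  })
  scan <- do.call(rbind, rows)
  attr(scan, "parameter") <- parameter
  attr(scan, "params") <- params
  attr(scan, "base_scenario") <- base_scenario
  class(scan) <- c("icg_scan", "data.frame")
  scan
}

#' Trial clamping versus resection
#'
#' For each fraction x, runs one simulation with hepatic blood flow clamped
#' to \code{1 - x} of its reference value (intraoperative trial clamping of
#' the liver volume scheduled for resection) and one with
#' \code{resection_rate = x} (the tissue actually removed), under each
#' requested cirrhosis degree, and pairs the resulting plasma disappearance
#' rates.
#'
#' @param fractions clamped/resected fractions in [0, 0.9].
#' @param cirrhosis_degrees \code{f_cirrhosis} values (default: the CTP
#'   mapping).
#' @param params an \code{icg_parameters}.
#' @param protocol dosing protocol.
#' @param times simulation grid [min].
#' @return data.frame with columns \code{f_cirrhosis}, \code{fraction},
#'   \code{pdr_clamping}, \code{pdr_resection}, \code{r15_clamping},
#'   \code{r15_resection}.
#' @export
clamping_vs_resection <- function(fractions = seq(0, 0.9, by = 0.1),
                                  cirrhosis_degrees = ctp_mapping(),
                                  params = icg_parameters(),
                                  protocol = standard_bolus(),
                                  times = seq(0, 60, by = 0.1)) {
  stopifnot(all(fractions >= 0 & fractions <= 0.9))
  grid <- expand.grid(fraction = fractions, f_cirrhosis = cirrhosis_degrees,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- grid$fraction[i]
    fc <- grid$f_cirrhosis[i]
    pk_cl <- pk_parameters(simulate_icg(
      params, cirrhosis_scenario(fc, f_bloodflow = 1 - x + 1e-12),
      protocol, times))
    pk_rs <- pk_parameters(simulate_icg(
      params, cirrhosis_scenario(fc, resection_rate = x), protocol, times))
    data.frame(f_cirrhosis = fc, fraction = x,
               pdr_clamping = pk_cl$pdr, pdr_resection = pk_rs$pdr,
               r15_clamping = pk_cl$r15, r15_resection = pk_rs$r15)
  })
  do.call(rbind, res)
}

#' Invert a scan: map a clinical value back to the scanned parameter
#'
#' Monotone piecewise-linear interpolation of the scanned parameter at a
#' clinically measured pharmacokinetic value, e.g. the cirrhosis degree at
#' which the model reproduces an observed R15.
#'
#' @param scan an \code{icg_scan}.
#' @param pk_name column of the scan to invert (e.g. \code{"r15"},
#'   \code{"cl"}).
#' @param value clinical value of that parameter.
#' @return The interpolated scanned-parameter value.
#' @export
invert_scan <- function(scan, pk_name, value) {
  stopifnot(inherits(scan, "icg_scan"), pk_name %in% names(scan),
            length(value) == 1, is.finite(value))
  y <- scan[[pk_name]]
  d <- diff(y)
  if (!(all(d >= 0) || all(d <= 0))) {
    stop(sprintf("scan of %s is not monotone; cannot invert", pk_name),
         call. = FALSE)
  }
  if (value < min(y) || value > max(y)) {
    stop(sprintf("unmappable: %s = %g outside the scan range [%g, %g]",
                 pk_name, value, min(y), max(y)), call. = FALSE)
  }
  stats::approx(x = y, y = scan$value, xout = value, ties = "ordered")$y
}
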