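#' Write a simulated time course as CSV
#'
#' Comma-separated, dot decimal, mandatory header row. The resolved
#' configuration (parameters, scenario, protocol) is embedded as
#' \code{#}-prefixed comment lines above the header for reproducibility.
#'
#' @param tc an \code{icg_timecourse}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "icg_timecourse"))
  out <- data.frame(
    time_min = tc$time,
    cve_mg_per_l = tc$cve_mg_per_l,
    car_mg_per_l = tc$car_mg_per_l,
    chv_mg_per_l = tc$chv_mg_per_l,
    bile_excretion_mg_per_min = tc$bile_excretion_mg_per_min,
    extraction_ratio = tc$extraction_ratio,
    feces_mmole = tc$feces_mmole
  )
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- params_to_list(attr(tc, "params"), attr(tc, "scenario"))
  writeLines(sprintf("# %s: %.10g", names(cfg), unlist(cfg)), con)
  prot <- attr(tc, "protocol")
  writeLines(sprintf("# protocol_total_mg: %.10g", prot$total_mg), con)
  utils::write.table(out, con, sep = ",", dec = ".", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an observed plasma time course
#'
#' Two-column CSV with header \code{time_min, conc_mg_per_l};
#' \code{#}-prefixed comment lines are skipped.
#'
#' @param path CSV path.
#' @return List with \code{time} [min] and \code{conc} [mg/l], directly
#'   usable by [pk_parameters()].
#' @export
read_observed_timecourse <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_min", "conc_mg_per_l") %in% names(df))) {
    stop("expected columns time_min, conc_mg_per_l", call. = FALSE)
  }
  list(time = df$time_min, conc = df$conc_mg_per_l)
}

#' Write non-compartmental results as flat JSON
#'
#' @param pk an \code{icg_pk}.
#' @param path output path.
#' @param extra optional named list merged into the output (e.g. the
#'   scenario echo).
#' @return \code{path}, invisibly.
#' @export
write_pk_json <- function(pk, path, extra = NULL) {
  stopifnot(inherits(pk, "icg_pk"))
  x <- unclass(pk)
  x$window <- as.numeric(x$window)
  if (!is.null(extra)) x <- c(x, extra)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a dosing protocol from a configuration block
#'
#' Each event is a list with fields \code{kind} ("bolus" or "infusion"),
#' \code{amount} [mg] or \code{rate} [mg/min], optional \code{per_kg},
#' \code{start_min} and \code{duration_min}.
#'
#' @param events list of event lists (e.g. parsed from YAML).
#' @return A \code{dosing_protocol}.
#' @export
protocol_from_config <- function(events) {
  stopifnot(is.list(events), length(events) >= 1)
  dosing_protocol(lapply(events, function(ev) {
    kind <- match.arg(ev$kind, c("bolus", "infusion"))
    per_kg <- isTRUE(ev$per_kg)
    start <- if (is.null(ev$start_min)) 0 else ev$start_min
    if (kind == "bolus") {
      if (is.null(ev$amount)) stop("bolus event needs an amount",
                                   call. = FALSE)
      bolus_event(ev$amount, start = start,
                  duration = if (is.null(ev$duration_min)) NA
                             else ev$duration_min,
                  per_kg = per_kg)
    } else {
      if (is.null(ev$rate) || is.null(ev$duration_min)) {
        stop("infusion event needs a rate and duration_min", call. = FALSE)
      }
      infusion_event(ev$rate, start = start, duration = ev$duration_min,
                     per_kg = per_kg)
    }
  }))
}

#' Read a run configuration from YAML
#'
#' The configuration has optional blocks \code{parameters} (flat Table-style
#' keys, see [params_from_list()]), \code{scenario}, \code{protocol}
#' (list of dosing events, see [protocol_from_config()]), \code{grid}
#' (\code{t_end_min}, \code{step_min}) and \code{seed}. Unknown parameter
#' keys are rejected.
#'
#' @param path YAML path.
#' @return List with \code{params}, \code{scenario}, \code{protocol},
#'   \code{times}, \code{seed}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  flat <- c(if (!is.null(cfg$parameters)) cfg$parameters,
            if (!is.null(cfg$scenario)) cfg$scenario)
  ps <- if (length(flat)) params_from_list(flat) else
    list(params = icg_parameters(), scenario = scenario_parameters())
  protocol <- if (!is.null(cfg$protocol)) protocol_from_config(cfg$protocol)
              else standard_bolus()
  t_end <- if (!is.null(cfg$grid$t_end_min)) cfg$grid$t_end_min else 120
  step <- if (!is.null(cfg$grid$step_min)) cfg$grid$step_min else 0.1
  list(params = ps$params, scenario = ps$scenario, protocol = protocol,
       times = seq(0, t_end, by = step), seed = cfg$seed)
}

#' Write a scan table as CSV
#'
#' One row per grid value, one column per pharmacokinetic parameter, with
#' the scanned parameter name embedded as a comment header.
#'
#' @param scan an \code{icg_scan}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "icg_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scanned_parameter: %s", attr(scan, "parameter")),
             con)
  utils::write.table(as.data.frame(scan), con, sep = ",", dec = ".",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration dataset from a YAML manifest
#'
#' The manifest has a top-level \code{blocks} list; each block names a CSV
#' (columns \code{time_min}, \code{value} and optionally \code{sd}) and
#' carries \code{name}, \code{n_subjects}, \code{observable} (default
#' venous concentration), an optional \code{protocol} event list (see
#' [protocol_from_config()]) and an optional flat \code{scenario} block.
#' Relative CSV paths resolve against the manifest location.
#'
#' @param path manifest YAML path.
#' @return A \code{fit_dataset}.
#' @export
read_fit_dataset <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$blocks) || !length(cfg$blocks)) {
    stop("manifest has no blocks", call. = FALSE)
  }
  base_dir <- dirname(path)
  fit_dataset(lapply(cfg$blocks, function(b) {
    csv <- b$csv
    if (!file.exists(csv)) csv <- file.path(base_dir, b$csv)
    df <- utils::read.csv(csv, comment.char = "#")
    if (!all(c("time_min", "value") %in% names(df))) {
      stop("block CSV needs columns time_min, value: ", b$csv,
           call. = FALSE)
    }
    scenario <- if (is.null(b$scenario)) scenario_parameters() else
      do.call(scenario_parameters, b$scenario)
    fit_block(
      name = if (is.null(b$name)) basename(csv) else b$name,
      time = df$time_min, observed = df$value,
      sd = if ("sd" %in% names(df)) df$sd else NULL,
      protocol = if (is.null(b$protocol)) standard_bolus() else
        protocol_from_config(b$protocol),
      scenario = scenario,
      n_subjects = if (is.null(b$n_subjects)) 1 else b$n_subjects,
      observable = if (is.null(b$observable)) "cve_mg_per_l" else
        b$observable)
  }))
}
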