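#' Dosing events
#'
#' A dosing protocol is an ordered list of timed events. A bolus is modelled
#' as a constant-rate input over the injection duration (default: the
#' \code{ti_icg} injection time, 5 s), keeping the ODE system event-free
#' within integration segments; an infusion is a constant rate over its
#' duration. Rates of overlapping events add.
#'
#' @param amount bolus dose [mg], or [mg/kg] if \code{per_kg}.
#' @param rate infusion rate [mg/min].
#' @param start event start [min].
#' @param duration event duration [min]; for a bolus, \code{NA} defers to
#'   the injection time of the body parameter set.
#' @param per_kg logical; is the dose specified per kg body weight?
#' @return A \code{dose_event}.
#' @name dose-events
NULL

#' @rdname dose-events
#' @export
bolus_event <- function(amount, start = 0, duration = NA, per_kg = FALSE) {
  stopifnot(amount >= 0, start >= 0, is.na(duration) || duration > 0)
  structure(list(kind = "bolus", amount = amount, start = start,
                 duration = duration, per_kg = per_kg),
            class = "dose_event")
}

#' @rdname dose-events
#' @export
infusion_event <- function(rate, start = 0, duration, per_kg = FALSE) {
  stopifnot(rate >= 0, start >= 0, duration > 0)
  structure(list(kind = "infusion", rate = rate, start = start,
                 duration = duration, per_kg = per_kg),
            class = "dose_event")
}

#' Dosing protocol
#'
#' @param ... \code{dose_event}s (or a single list of them).
#' @return A \code{dosing_protocol} (unresolved: per-kg doses not yet bound
#'   to a body weight).
#' @export
#' @examples
#' # 0.5 mg/kg bolus over the default 5 s injection
#' standard_bolus()
#' # consecutive infusion protocol: 2.0 -> 0.5 -> 1.0 mg/min, 40 min each
#' dosing_protocol(infusion_event(2.0, 0, 40), infusion_event(0.5, 40, 40),
#'                 infusion_event(1.0, 80, 40))
dosing_protocol <- function(...) {
  events <- list(...)
  if (length(events) == 1L && !inherits(events[[1L]], "dose_event")) {
    events <- events[[1L]]
  }
  stopifnot(all(vapply(events, inherits, TRUE, "dose_event")))
  structure(list(events = events, resolved = FALSE),
            class = "dosing_protocol")
}

#' @rdname dosing_protocol
#' @param dose_per_kg bolus dose [mg/kg].
#' @param start start time [min].
#' @export
standard_bolus <- function(dose_per_kg = 0.5, start = 0) {
  dosing_protocol(bolus_event(dose_per_kg, start = start, per_kg = TRUE))
}

#' Constant-infusion protocol with optional priming dose
#'
#' @param rate infusion rate [mg/min].
#' @param duration infusion duration [min].
#' @param priming_mg optional priming bolus [mg] at start.
#' @export
infusion_protocol <- function(rate, duration = 120, priming_mg = NULL) {
  ev <- list(infusion_event(rate, 0, duration))
  if (!is.null(priming_mg)) ev <- c(list(bolus_event(priming_mg)), ev)
  dosing_protocol(ev)
}

#' Resolve a protocol against a body
#'
#' Binds per-kg doses to the body weight and fills unspecified bolus
#' durations with the injection time \code{ti_icg}. Resolution is
#' idempotent.
#'
#' @param protocol a \code{dosing_protocol}.
#' @param body an \code{icg_body}.
#' @return The resolved protocol, with absolute amounts [mg] and total dose
#'   metadata (\code{total_mg}, \code{total_mmole}).
#' @export
resolve_protocol <- function(protocol, body = body_parameters()) {
  stopifnot(inherits(protocol, "dosing_protocol"))
  if (isTRUE(protocol$resolved)) return(protocol)
  ti_min <- body$ti_icg / 60
  events <- lapply(protocol$events, function(ev) {
    if (isTRUE(ev$per_kg)) {
      if (is.null(body$BW) || body$BW <= 0) {
        stop("per-kg dose cannot be resolved without a body weight",
             call. = FALSE)
      }
      if (ev$kind == "bolus") ev$amount <- ev$amount * body$BW
      else ev$rate <- ev$rate * body$BW
      ev$per_kg <- FALSE
    }
    if (ev$kind == "bolus" && is.na(ev$duration)) ev$duration <- ti_min
    ev
  })
  total_mg <- sum(vapply(events, function(ev) {
    if (ev$kind == "bolus") ev$amount else ev$rate * ev$duration
  }, 0))
  structure(list(events = events, resolved = TRUE, total_mg = total_mg,
                 total_mmole = mg_to_mmole(total_mg, body$Mr_icg),
                 Mr_icg = body$Mr_icg),
            class = "dosing_protocol")
}

#' Input rate of a resolved protocol
#'
#' @param protocol a resolved \code{dosing_protocol}.
#' @param t time [min] (vectorized).
#' @return Input rate [mmole/min]. A bolus of D mg over duration d
#'   contributes D/d mg/min on \code{[start, start + d)}; overlapping
#'   events add; the integral over all time equals the total resolved dose
#'   exactly.
#' @export
protocol_input_rate <- function(protocol, t) {
  stopifnot(isTRUE(protocol$resolved))
  rate_mg <- vapply(t, function(tt) {
    sum(vapply(protocol$events, function(ev) {
      r <- if (ev$kind == "bolus") ev$amount / ev$duration else ev$rate
      if (tt >= ev$start && tt < ev$start + ev$duration) r else 0
    }, 0))
  }, 0)
  rate_mg / protocol$Mr_icg
}

#' Breakpoints of a resolved protocol
#'
#' Times at which the input rate is discontinuous; the integrator is
#' restarted at each of them.
#'
#' @param protocol a resolved \code{dosing_protocol}.
#' @return Sorted unique numeric vector of times [min].
#' @export
protocol_breakpoints <- function(protocol) {
  stopifnot(isTRUE(protocol$resolved))
  sort(unique(unlist(lapply(protocol$events, function(ev) {
    c(ev$start, ev$start + ev$duration)
  }))))
}

#' @export
print.dosing_protocol <- function(x, ...) {
  cat(sprintf("ICG dosing protocol (%s)\n",
              if (isTRUE(x$resolved)) sprintf("resolved, %.2f mg total",
                                              x$total_mg)
              else "unresolved"))
  for (ev in x$events) {
    if (ev$kind == "bolus") {
      cat(sprintf("  bolus %.3g %s at %.2f min%s\n", ev$amount,
                  if (isTRUE(ev$per_kg)) "mg/kg" else "mg", ev$start,
                  if (is.na(ev$duration)) ""
                  else sprintf(" over %.3g min", ev$duration)))
    } else {
      cat(sprintf("  infusion %.3g %s for %.3g min from %.2f min\n", ev$rate,
                  if (isTRUE(ev$per_kg)) "mg/min/kg" else "mg/min",
                  ev$duration, ev$start))
    }
  }
  invisible(x)
}
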