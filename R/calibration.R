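# the five hepatic kinetic constants determined from data
FIT_PARAMETERS <- c("ICGIM_Vmax", "ICGIM_Km", "ICGLI2CA_Vmax",
                    "ICGLI2CA_Km", "ICGLI2BI_k")

#' Calibration data block
#'
#' One block couples an observed time course (one observable from one
#' study arm) with the protocol and scenario needed to simulate it.
#'
#' @param name block label.
#' @param time observation times [min].
#' @param observed observed values (units of the observable column).
#' @param sd optional per-point standard deviations; per-point weights
#'   default to \code{1/sd} when given, else 1.
#' @param protocol the study's dosing protocol.
#' @param scenario scenario of the study arm.
#' @param n_subjects number of subjects behind the time course; blocks are
#'   weighted by it.
#' @param observable column of the simulated time course to compare
#'   against (default venous concentration [mg/l]).
#' @return A \code{fit_block}.
#' @export
fit_block <- function(name, time, observed, sd = NULL,
                      protocol = standard_bolus(),
                      scenario = scenario_parameters(),
                      n_subjects = 1,
                      observable = "cve_mg_per_l") {
  stopifnot(length(time) == length(observed), all(time >= 0),
            all(diff(time) > 0), n_subjects > 0)
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(observed), all(sd > 0))
  }
  structure(list(name = name, time = time, observed = observed, sd = sd,
                 protocol = protocol, scenario = scenario,
                 n_subjects = n_subjects, observable = observable),
            class = "fit_block")
}

#' Calibration dataset
#'
#' @param ... \code{fit_block}s (or one list of them).
#' @return A \code{fit_dataset}.
#' @export
fit_dataset <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "fit_block")) {
    blocks <- blocks[[1L]]
  }
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, TRUE, "fit_block")))
  structure(list(blocks = blocks), class = "fit_dataset")
}

simulate_block <- function(block, params) {
  t_end <- max(block$time)
  times <- sort(unique(c(0, block$time, t_end)))
  tc <- simulate_icg(params, block$scenario, block$protocol, times)
  stats::approx(tc$time, tc[[block$observable]], xout = block$time)$y
}

with_fit_parameters <- function(params, p) {
  stopifnot(all(names(p) %in% FIT_PARAMETERS))
  tp <- unclass(params$transporters)
  for (nm in names(p)) tp[[nm]] <- p[[nm]]
  # re-validates positivity, so pathological candidates fail loudly
  params$transporters <- do.call(transporter_parameters, tp)
  params
}

# weighted residual vector; squared sum gives the objective
fit_residuals <- function(p, data, params) {
  unlist(lapply(data$blocks, function(block) {
    m <- simulate_block(block, with_fit_parameters(params, p))
    w_ik <- if (is.null(block$sd)) rep(1, length(block$observed))
            else 1 / block$sd
    sqrt(block$n_subjects / length(block$observed)) *
      w_ik * (block$observed - m)
  }), use.names = FALSE)
}

#' Weighted least-squares objective
#'
#' Cost of a candidate set of hepatic kinetic constants against a
#' calibration dataset:
#' \deqn{F = \sum_k \frac{w_k}{n_k} \sum_i \big(w_{i,k}\,(y_{i,k} -
#'   m_{i,k})\big)^2}
#' with \eqn{m_{i,k}} the model prediction, per-point weights
#' \eqn{w_{i,k}} (1/SD when errors are given, else 1), block weights
#' \eqn{w_k} equal to the number of subjects, and \eqn{n_k} the number of
#' points in block k. The cost is zero exactly when all residuals vanish
#' and is invariant to the ordering of blocks.
#'
#' @param p named numeric vector over (a subset of) the five fitted
#'   constants: \code{ICGIM_Vmax}, \code{ICGIM_Km}, \code{ICGLI2CA_Vmax},
#'   \code{ICGLI2CA_Km}, \code{ICGLI2BI_k}.
#' @param data a \code{fit_dataset}.
#' @param params base parameter bundle supplying everything not fitted.
#' @return Non-negative scalar cost; \code{Inf} (with a
#'   \code{"diagnostics"} attribute) if a simulation fails.
#' @export
fit_objective <- function(p, data, params = icg_parameters()) {
  r <- tryCatch(fit_residuals(p, data, params), error = identity)
  if (inherits(r, "error")) {
    return(structure(Inf, diagnostics = conditionMessage(r)))
  }
  sum(r^2)
}

#' Multi-start calibration of the hepatic transport parameters
#'
#' Minimizes [fit_objective()] over the five hepatic kinetic constants by
#' bounded local least squares (Levenberg-Marquardt,
#' \code{minpack.lm::nls.lm}) restarted from multiple start points drawn
#' log-uniformly within the bounds. Parameters are optimized on the log
#' scale (they are positive scale parameters). Deterministic under
#' \code{seed}.
#'
#' @param data a \code{fit_dataset}.
#' @param params base parameter bundle; its transporter values are the
#'   centre of the default bounds.
#' @param n_starts number of local optimizations (the reference
#'   calibration used 250).
#' @param bounds_factor lower/upper multiplicative bounds around the base
#'   values.
#' @param seed integer seed (mandatory).
#' @param maxiter per-start iteration cap.
#' @return An object of class \code{icg_fit}: best parameter vector
#'   \code{par}, best \code{objective}, per-start table \code{starts}
#'   (start values, final values, objective, convergence flag), and the
#'   seed.
#' @export
fit_transporters <- function(data, params = icg_parameters(),
                             n_starts = 25,
                             bounds_factor = c(0.01, 100),
                             seed, maxiter = 50) {
  if (missing(seed)) stop("a seed is mandatory for multi-start fitting",
                          call. = FALSE)
  stopifnot(n_starts >= 1, bounds_factor[1] > 0,
            bounds_factor[1] < bounds_factor[2],
            is.finite(bounds_factor[2]))
  base <- unlist(params$transporters[FIT_PARAMETERS])
  lower <- log(base * bounds_factor[1])
  upper <- log(base * bounds_factor[2])

  set.seed(seed)
  start_mat <- matrix(stats::runif(n_starts * length(base), rep(lower, each = n_starts),
                                   rep(upper, each = n_starts)),
                      nrow = n_starts,
                      dimnames = list(NULL, FIT_PARAMETERS))

  resid_log <- function(lp) {
    p <- stats::setNames(exp(lp), FIT_PARAMETERS)
    r <- tryCatch(fit_residuals(p, data, params), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) {
      # penalize pathological parameter regions without aborting the start
      return(rep(1e6, n_resid))
    }
    r
  }
  n_resid <- sum(vapply(data$blocks, function(b) length(b$observed), 0L))

  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      # epsfcn reflects the ODE-solution accuracy: forward-difference
      # steps below it produce a noise-dominated Jacobian and stall the
      # Levenberg-Marquardt iteration
      # iteration-cap warnings are redundant: the per-start `converged`
      # flag records them
      suppressWarnings(
        minpack.lm::nls.lm(par = start_mat[s, ], fn = resid_log,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, epsfcn = 1e-6))),
      error = function(e) NULL
    )
    starts[[s]] <- if (is.null(fit)) {
      data.frame(start = s, objective = Inf, converged = FALSE,
                 t(stats::setNames(rep(NA_real_, length(base)),
                                   FIT_PARAMETERS)))
    } else {
      data.frame(start = s, objective = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4,
                 t(stats::setNames(exp(fit$par), FIT_PARAMETERS)))
    }
  }
  starts <- do.call(rbind, starts)
  if (all(!is.finite(starts$objective))) {
    stop("all optimization starts failed", call. = FALSE)
  }
  best <- which.min(starts$objective)
  par <- stats::setNames(unlist(starts[best, FIT_PARAMETERS]),
                         FIT_PARAMETERS)
  structure(list(par = par, objective = starts$objective[best],
                 starts = starts, best_start = best, seed = seed,
                 n_starts = n_starts,
                 bounds = rbind(lower = exp(lower), upper = exp(upper))),
            class = "icg_fit")
}

#' @export
print.icg_fit <- function(x, ...) {
  cat(sprintf("ICG transporter calibration: %d starts, best objective %.6g (start %d, seed %d)\n",
              x$n_starts, x$objective, x$best_start, x$seed))
  print(round(x$par, 6))
  disp <- apply(log(x$starts[is.finite(x$starts$objective) &
                               x$starts$objective <= 1.01 * x$objective,
                             FIT_PARAMETERS, drop = FALSE]),
                2, stats::sd)
  cat("log-scale dispersion across near-optimal starts (identifiability):\n")
  print(round(disp, 4))
  invisible(x)
}
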