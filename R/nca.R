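#' Fit the elimination rate constant
#'
#' Fits the monoexponential decay \eqn{c(t) = c(0) e^{-k_{el} t}} by
#' log-linear least squares within a time window. The window defaults to
#' 5--15 min after dose start, the early monoexponential phase over which
#' the plasma disappearance rate is clinically determined.
#'
#' @param time time points [min].
#' @param conc plasma concentrations [mg/l].
#' @param window two-element numeric, fit window [min].
#' @return List with \code{kel} [1/min], the back-extrapolated intercept
#'   \code{c0} [mg/l], \code{r_squared} of the log-linear fit and the
#'   window used.
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.5)
#' fit_kel(t, 2 * exp(-0.25 * t))$kel   # 0.25
fit_kel <- function(time, conc, window = c(5, 15)) {
  stopifnot(length(time) == length(conc), length(window) == 2,
            window[1] < window[2])
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 3) {
    stop("window unusable: fewer than 3 samples inside the fit window",
         call. = FALSE)
  }
  if (any(conc[sel] <= 0)) {
    stop("window unusable: non-positive concentrations inside the fit window",
         call. = FALSE)
  }
  fit <- stats::lm(log(conc[sel]) ~ time[sel])
  lc <- log(conc[sel])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((lc - mean(lc))^2)
  list(kel = -unname(stats::coef(fit)[2L]),
       c0 = exp(unname(stats::coef(fit)[1L])),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       window = window)
}

#' Area under the curve, extrapolated to infinity
#'
#' Trapezoidal rule over the observed span plus the monoexponential tail
#' \code{c_last / kel}.
#'
#' @inheritParams fit_kel
#' @param kel elimination rate constant [1/min], must be positive.
#' @return AUC to infinity [mg min/l].
#' @export
auc_infinity <- function(time, conc, kel) {
  stopifnot(length(time) == length(conc), all(diff(time) > 0))
  if (!is.finite(kel) || kel <= 0) {
    stop("kel must be positive for extrapolation to infinity", call. = FALSE)
  }
  auc_obs <- sum(diff(time) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  auc_obs + conc[length(conc)] / kel
}

#' Non-compartmental ICG pharmacokinetic parameters
#'
#' Computes the standard clinical ICG parameters from a plasma
#' concentration time course:
#' \itemize{
#'   \item \code{kel} [1/min] from the log-linear fit (see [fit_kel()]);
#'   \item plasma disappearance rate \code{pdr = 100 kel} [%/min];
#'   \item half-life \code{t_half = ln(2)/kel} [min];
#'   \item \code{auc_inf} [mg min/l] by trapezoid + tail;
#'   \item apparent volume of distribution \code{vd = D/(auc_inf kel)} [l];
#'   \item clearance \code{cl = vd kel} [l/min];
#'   \item retention ratios \code{r15 = c(15)/c_max} and
#'     \code{r20 = c(20)/c_max} [-], with \code{c_max} the sampled maximum
#'     concentration (not a back-extrapolated intercept).
#' }
#'
#' @param tc an \code{icg_timecourse} (venous concentration is used) or a
#'   data.frame/list with elements \code{time} [min] and \code{conc}
#'   [mg/l].
#' @param dose administered dose [mg]; taken from the protocol metadata of
#'   a simulated time course when omitted.
#' @param window kel fit window [min].
#' @return An object of class \code{icg_pk} (named list; also contains
#'   \code{cl_ml_per_min}, \code{r15_percent}, \code{cmax}, \code{dose},
#'   \code{window} and the fit's \code{r_squared}).
#' @export
pk_parameters <- function(tc, dose = NULL, window = c(5, 15)) {
  if (inherits(tc, "icg_timecourse")) {
    time <- tc$time
    conc <- tc$cve_mg_per_l
    if (is.null(dose)) dose <- attr(tc, "protocol")$total_mg
  } else {
    time <- tc$time
    conc <- tc$conc
  }
  if (is.null(dose) || !is.finite(dose) || dose <= 0) {
    stop("a positive dose [mg] is required", call. = FALSE)
  }
  fit <- fit_kel(time, conc, window)
  kel <- fit$kel
  auc <- auc_infinity(time, conc, kel)
  vd <- dose / (auc * kel)
  cl <- vd * kel
  cmax <- max(conc)
  conc_at <- function(tt) {
    if (tt > max(time)) cmax * NA_real_
    else stats::approx(time, conc, xout = tt)$y
  }
  r15 <- conc_at(15) / cmax
  r20 <- conc_at(20) / cmax
  structure(list(
    kel = kel, pdr = 100 * kel, t_half = log(2) / kel,
    auc_inf = auc, vd = vd, cl = cl, cl_ml_per_min = 1000 * cl,
    r15 = r15, r15_percent = 100 * r15, r20 = r20,
    cmax = cmax, dose = dose, window = window,
    r_squared = fit$r_squared
  ), class = "icg_pk")
}

#' @export
print.icg_pk <- function(x, ...) {
  cat("ICG non-compartmental parameters\n")
  cat(sprintf("  kel    %8.4f 1/min   (PDR %.2f %%/min, R^2 %.4f, window %g-%g min)\n",
              x$kel, x$pdr, x$r_squared, x$window[1], x$window[2]))
  cat(sprintf("  t_half %8.3f min\n", x$t_half))
  cat(sprintf("  CL     %8.4f l/min   (Vd %.3f l, AUCinf %.2f mg min/l, dose %.1f mg)\n",
              x$cl, x$vd, x$auc_inf, x$dose))
  cat(sprintf("  R15    %8.4f         (%.2f %%; cmax %.2f mg/l)   R20 %.4f\n",
              x$r15, x$r15_percent, x$cmax, x$r20))
  invisible(x)
}

#' @export
as.data.frame.icg_pk <- function(x, ...) {
  data.frame(kel = x$kel, pdr = x$pdr, t_half = x$t_half,
             auc_inf = x$auc_inf, vd = x$vd, cl = x$cl, r15 = x$r15,
             r20 = x$r20, cmax = x$cmax, dose = x$dose,
             r_squared = x$r_squared)
}
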