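#' Configuration of the synthetic surgical cohort generator
#'
#' The generator emulates the statistical structure a survival
#' classification analysis of partial hepatectomy assumes: every patient
#' has a latent cirrhosis degree and a planned resection rate; the
#' preoperative liver function test (R15) is the model's R15 at the latent
#' cirrhosis degree, observed with multiplicative measurement noise; death
#' is driven by the \emph{true} postoperative R15 through a logistic link.
#' Defaults produce cohorts of 141 patients with roughly the 109/32
#' survivor/non-survivor composition of the reference surgical dataset.
#'
#' @param n patient count (at least 20).
#' @param seed integer seed (mandatory).
#' @param cirrhosis_shape shape parameters of the Beta distribution of the
#'   latent cirrhosis degree (scaled to [0, cirrhosis_max]). The default
#'   is calibrated by quadrature so that the expected non-survivor
#'   fraction matches the 32/141 composition of the reference cohort.
#' @param cirrhosis_max upper bound of the cirrhosis degree.
#' @param resection_range uniform range of the resection rate.
#' @param noise_cv coefficient of variation of the lognormal measurement
#'   noise on the preoperative R15.
#' @param death_midpoint postoperative R15 at which the death probability
#'   is 50%.
#' @param death_scale logistic scale of the death model.
#' @return A \code{cohort_config}.
#' @export
cohort_config <- function(n = 141, seed,
                          cirrhosis_shape = c(1.40, 1.55),
                          cirrhosis_max = 0.9,
                          resection_range = c(0.05, 0.75),
                          noise_cv = 0.10,
                          death_midpoint = 0.35,
                          death_scale = 0.07) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n >= 20, all(cirrhosis_shape > 0),
            cirrhosis_max > 0, cirrhosis_max <= 0.9,
            resection_range[1] >= 0, resection_range[2] <= 0.9,
            resection_range[1] < resection_range[2],
            noise_cv >= 0, death_midpoint > 0, death_midpoint < 1,
            death_scale > 0)
  structure(list(n = n, seed = seed, cirrhosis_shape = cirrhosis_shape,
                 cirrhosis_max = cirrhosis_max,
                 resection_range = resection_range, noise_cv = noise_cv,
                 death_midpoint = death_midpoint,
                 death_scale = death_scale),
            class = "cohort_config")
}

#' Generate a synthetic surgical cohort
#'
#' Draws latent cirrhosis degrees and resection rates, computes true
#' preoperative and postoperative R15 values through the PBPK model
#' (via a precomputed surface by default, see [r15_surface()]), applies
#' mean-preserving lognormal measurement noise to the preoperative value
#' and draws survival from the logistic death model on the true
#' postoperative R15. Fully reproducible under the config seed.
#'
#' @param config a \code{cohort_config}.
#' @param surface an \code{icg_r15_surface}; computed on demand (slow) if
#'   omitted.
#' @return data.frame with columns \code{patient_id}, \code{preop_r15},
#'   \code{resection_rate}, \code{survived} (0/1); the hidden ground truth
#'   (\code{f_cirrhosis_true}, \code{preop_r15_true},
#'   \code{postop_r15_true}, \code{p_death}) is attached as the
#'   \code{"truth"} attribute and never used by the classifiers.
#' @export
generate_cohort <- function(config, surface = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(surface)) surface <- r15_surface()
  set.seed(config$seed)
  n <- config$n
  f_true <- config$cirrhosis_max *
    stats::rbeta(n, config$cirrhosis_shape[1], config$cirrhosis_shape[2])
  rr <- stats::runif(n, config$resection_range[1], config$resection_range[2])
  preop_true <- lookup_r15(surface, f_true, 0)
  postop_true <- lookup_r15(surface, f_true, rr)
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    preop_obs <- preop_true * stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                            sdlog = sdlog)
  } else {
    preop_obs <- preop_true
  }
  preop_obs <- pmin(preop_obs, 0.999)
  p_death <- stats::plogis((postop_true - config$death_midpoint) /
                             config$death_scale)
  died <- stats::rbinom(n, 1, p_death)
  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    preop_r15 = preop_obs,
    resection_rate = rr,
    survived = 1L - died
  )
  attr(cohort, "truth") <- data.frame(
    patient_id = cohort$patient_id,
    f_cirrhosis_true = f_true,
    preop_r15_true = preop_true,
    postop_r15_true = postop_true,
    p_death = p_death
  )
  attr(cohort, "config") <- config
  cohort
}

#' Write / read a cohort as CSV
#'
#' The cohort CSV has columns \code{patient_id}, \code{preop_r15}
#' (fraction), \code{resection_rate} (fraction), \code{survived} (0/1).
#' The optional ground-truth sidecar is written for recovery analyses only
#' and is never read by the classifiers.
#'
#' @param cohort data.frame from [generate_cohort()] (or equivalent).
#' @param path output CSV path.
#' @param truth_path optional path of the ground-truth sidecar.
#' @return \code{path}, invisibly.
#' @export
export_cohort <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(
    cohort[, c("patient_id", "preop_r15", "resection_rate", "survived")],
    path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    truth <- attr(cohort, "truth")
    if (is.null(truth)) stop("cohort carries no ground truth", call. = FALSE)
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname export_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "preop_r15", "resection_rate", "survived")
  if (!all(need %in% names(cohort))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cohort$survived %in% c(0L, 1L))) {
    stop("survived must be 0/1", call. = FALSE)
  }
  cohort
}
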