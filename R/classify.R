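#' Coefficients of the cirrhosis-degree map
#'
#' The cirrhosis degree is estimated from a measured preoperative retention
#' ratio through the logarithmic map
#' \deqn{f_{cirrhosis} = a\,\ln(b\,R15_{preop}) + c.}
#' Only the slope \code{a} and the effective intercept \code{a ln(b) + c}
#' are identifiable from a scan fit; \code{(b, c)} individually lie on a
#' degenerate ridge.
#'
#' @param a slope coefficient.
#' @param b inner scale coefficient, must be positive.
#' @param c offset coefficient.
#' @return An object of class \code{icg_map} with fields \code{a},
#'   \code{b}, \code{c} and the effective \code{intercept}.
#' @export
map_coefficients <- function(a, b = 1, c = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), b > 0)
  structure(list(a = a, b = b, c = c, intercept = a * log(b) + c),
            class = "icg_map")
}

#' Fit the cirrhosis-degree map to a model scan
#'
#' Least-squares fit of \code{f_cirrhosis = a ln(b R15) + c} to the
#' model-predicted dependency of R15 on the cirrhosis degree. Since the map
#' is affine in \code{ln(R15)}, the fit is a linear regression of the
#' scanned cirrhosis degree on \code{ln(R15)}; the slope \code{a} is
#' uniquely identified and the intercept is reported with \code{b = 1}.
#'
#' @param scan an \code{icg_scan} over \code{f_cirrhosis} containing an
#'   \code{r15} column.
#' @return An \code{icg_map}.
#' @export
fit_map_coefficients <- function(scan) {
  stopifnot(inherits(scan, "icg_scan"))
  if (!identical(attr(scan, "parameter"), "f_cirrhosis")) {
    stop("map coefficients are fit to an f_cirrhosis scan", call. = FALSE)
  }
  r15 <- scan$r15
  f <- scan$value
  if (any(!is.finite(r15)) || any(r15 <= 0) || length(unique(r15)) < 3) {
    stop("degenerate scan: R15 must be positive and non-constant",
         call. = FALSE)
  }
  if (any(diff(r15) <= 0)) {
    stop("non-monotone scan: R15 must increase with the cirrhosis degree",
         call. = FALSE)
  }
  fit <- stats::lm(f ~ log(r15))
  map_coefficients(a = unname(stats::coef(fit)[2L]), b = 1,
                   c = unname(stats::coef(fit)[1L]))
}

#' Estimate the cirrhosis degree from a preoperative R15
#'
#' Evaluates the logarithmic map and clamps the result to the admissible
#' scenario range (healthy subjects otherwise map below zero).
#'
#' @param r15_preop measured preoperative retention ratio, fraction in
#'   (0, 1); vectorized.
#' @param coeffs an \code{icg_map}.
#' @param clamp admissible range of the cirrhosis degree.
#' @return Estimated \code{f_cirrhosis}, clamped.
#' @export
#' @examples
#' estimate_fcirrhosis(0.10, map_coefficients(0.312, 1.693, 0.861))
estimate_fcirrhosis <- function(r15_preop, coeffs, clamp = c(0, 0.9)) {
  stopifnot(inherits(coeffs, "icg_map"))
  if (any(!is.finite(r15_preop)) || any(r15_preop <= 0)) {
    stop("R15 must be positive", call. = FALSE)
  }
  raw <- coeffs$a * log(coeffs$b * r15_preop) + coeffs$c
  pmin(pmax(raw, clamp[1]), clamp[2])
}

r15_of_timecourse <- function(tc) {
  stats::approx(tc$time, tc$cve_mg_per_l, xout = 15)$y / max(tc$cve_mg_per_l)
}

#' Precomputed R15 surface over cirrhosis degree and resection rate
#'
#' Simulating a standard bolus for every patient is wasteful when many
#' postoperative predictions are needed; this precomputes R15 on a regular
#' (f_cirrhosis x resection_rate) grid (default step 0.05 on both axes)
#' and interpolates bilinearly. The R15 surface is smooth, so the
#' interpolation error is far below clinical measurement noise.
#'
#' @param params an \code{icg_parameters}.
#' @param protocol dosing protocol.
#' @param f_grid,rr_grid grid axes.
#' @param times simulation grid [min]; only the first 16 min are needed
#'   for R15.
#' @return An object of class \code{icg_r15_surface}; call it via
#'   [lookup_r15()].
#' @export
r15_surface <- function(params = icg_parameters(),
                        protocol = standard_bolus(),
                        f_grid = seq(0, 0.9, by = 0.05),
                        rr_grid = seq(0, 0.9, by = 0.05),
                        times = seq(0, 16, by = 0.1)) {
  stopifnot(all(diff(f_grid) > 0), all(diff(rr_grid) > 0))
  m <- matrix(NA_real_, length(f_grid), length(rr_grid))
  for (i in seq_along(f_grid)) {
    for (j in seq_along(rr_grid)) {
      tc <- simulate_icg(params,
                         cirrhosis_scenario(f_grid[i],
                                            resection_rate = rr_grid[j]),
                         protocol, times)
      m[i, j] <- r15_of_timecourse(tc)
    }
  }
  structure(list(f_grid = f_grid, rr_grid = rr_grid, r15 = m,
                 params = params),
            class = "icg_r15_surface")
}

#' Bilinear lookup on an R15 surface
#'
#' @param surface an \code{icg_r15_surface}.
#' @param f_cirrhosis,resection_rate query points (vectorized, recycled).
#' @return Interpolated R15 values.
#' @export
lookup_r15 <- function(surface, f_cirrhosis, resection_rate = 0) {
  stopifnot(inherits(surface, "icg_r15_surface"))
  n <- max(length(f_cirrhosis), length(resection_rate))
  f <- rep_len(f_cirrhosis, n)
  rr <- rep_len(resection_rate, n)
  fg <- surface$f_grid; rg <- surface$rr_grid
  if (any(f < fg[1] | f > fg[length(fg)] |
          rr < rg[1] | rr > rg[length(rg)])) {
    stop("query outside the precomputed surface", call. = FALSE)
  }
  i <- pmin(findInterval(f, fg), length(fg) - 1L)
  j <- pmin(findInterval(rr, rg), length(rg) - 1L)
  tf <- (f - fg[i]) / (fg[i + 1L] - fg[i])
  tr <- (rr - rg[j]) / (rg[j + 1L] - rg[j])
  m <- surface$r15
  (1 - tf) * (1 - tr) * m[cbind(i, j)] +
    tf * (1 - tr) * m[cbind(i + 1L, j)] +
    (1 - tf) * tr * m[cbind(i, j + 1L)] +
    tf * tr * m[cbind(i + 1L, j + 1L)]
}

#' Predict the postoperative R15
#'
#' Simulates (or interpolates) a standard bolus with both the cirrhosis
#' degree and the resection rate applied and returns the resulting
#' retention ratio -- the model-based estimate of the liver function test
#' on the first postoperative day.
#'
#' @param f_cirrhosis cirrhosis degree(s) in [0, 0.9].
#' @param resection_rate resection rate(s) in [0, 0.9].
#' @param surface optional \code{icg_r15_surface} for fast interpolation;
#'   when \code{NULL} every query is simulated exactly.
#' @param params,protocol,times used for exact simulation.
#' @return Predicted postoperative R15 (fraction).
#' @export
predict_postop_r15 <- function(f_cirrhosis, resection_rate,
                               surface = NULL,
                               params = icg_parameters(),
                               protocol = standard_bolus(),
                               times = seq(0, 16, by = 0.1)) {
  if (!is.null(surface)) {
    return(lookup_r15(surface, f_cirrhosis, resection_rate))
  }
  n <- max(length(f_cirrhosis), length(resection_rate))
  f <- rep_len(f_cirrhosis, n)
  rr <- rep_len(resection_rate, n)
  vapply(seq_len(n), function(k) {
    tc <- simulate_icg(params,
                       cirrhosis_scenario(f[k], resection_rate = rr[k]),
                       protocol, times)
    r15_of_timecourse(tc)
  }, 0)
}

CLASSIFIER_MODELS <- c("Data1A", "Data1B", "Data2", "PBPK1", "PBPK2")

#' Build classifier features for a surgical cohort
#'
#' Feature definitions of the five survival classifiers:
#' \describe{
#'   \item{Data1A}{preoperative R15.}
#'   \item{Data1B}{calculated postoperative R15: preoperative R15 times
#'     the future liver remnant (1 - resection rate).}
#'   \item{Data2}{preoperative R15 and resection rate.}
#'   \item{PBPK1}{model-predicted postoperative R15 (cirrhosis degree
#'     estimated from preoperative R15 via the logarithmic map, then a
#'     simulated hepatectomy at the patient's resection rate).}
#'   \item{PBPK2}{estimated cirrhosis degree and resection rate.}
#' }
#' The positive class is non-survival.
#'
#' @param cohort data.frame with columns \code{preop_r15} (fraction),
#'   \code{resection_rate} (fraction) and \code{survived} (0/1).
#' @param model one of \code{"Data1A"}, \code{"Data1B"}, \code{"Data2"},
#'   \code{"PBPK1"}, \code{"PBPK2"}.
#' @param coeffs \code{icg_map} for the PBPK models.
#' @param surface \code{icg_r15_surface} for fast postoperative
#'   prediction (PBPK1).
#' @return List with the feature matrix \code{x} and the label factor
#'   \code{y} (levels \code{survivor}, \code{nonsurvivor}).
#' @export
build_features <- function(cohort, model, coeffs = NULL, surface = NULL) {
  model <- match.arg(model, CLASSIFIER_MODELS)
  stopifnot(all(c("preop_r15", "resection_rate", "survived") %in%
                  names(cohort)))
  r15 <- cohort$preop_r15
  rr <- cohort$resection_rate
  if (model %in% c("PBPK1", "PBPK2")) {
    if (is.null(coeffs)) {
      stop("PBPK feature models require map coefficients", call. = FALSE)
    }
    f_est <- estimate_fcirrhosis(r15, coeffs)
  }
  x <- switch(model,
    Data1A = cbind(preop_r15 = r15),
    Data1B = cbind(calc_postop_r15 = r15 * (1 - rr)),
    Data2  = cbind(preop_r15 = r15, resection_rate = rr),
    PBPK1  = cbind(pred_postop_r15 = predict_postop_r15(f_est, rr,
                                                        surface = surface)),
    PBPK2  = cbind(f_cirrhosis = f_est, resection_rate = rr)
  )
  y <- factor(ifelse(cohort$survived == 1, "survivor", "nonsurvivor"),
              levels = c("survivor", "nonsurvivor"))
  list(x = x, y = y, model = model)
}

#' Metrics from a confusion matrix
#'
#' Positive class is non-survival. Undefined ratios (0/0) are \code{NA}.
#'
#' @param tp,fp,fn,tn confusion-matrix counts.
#' @return Named numeric: precision (PPV), recall, specificity, NPV,
#'   balanced accuracy, F1.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b > 0) a / b else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(precision = precision, recall = recall, specificity = specificity,
    npv = npv, balanced_accuracy = (recall + specificity) / 2, f1 = f1)
}

# fit the SVM and return predicted classes + oriented decision scores
svm_predict <- function(x_train, y_train, x_test, degree, cost) {
  fit <- e1071::svm(x_train, y_train, kernel = "polynomial",
                    degree = degree, cost = cost, scale = TRUE)
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient the score so that larger values favour the positive class
  first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
  score <- if (first == "nonsurvivor") dv[, 1L] else -dv[, 1L]
  list(class = pred, score = unname(score))
}

roc_auc <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = score,
    levels = c("survivor", "nonsurvivor"), direction = "<", quiet = TRUE)))
}

classification_metrics <- function(y, pred_class, score) {
  tp <- sum(pred_class == "nonsurvivor" & y == "nonsurvivor")
  fp <- sum(pred_class == "nonsurvivor" & y == "survivor")
  fn <- sum(pred_class == "survivor" & y == "nonsurvivor")
  tn <- sum(pred_class == "survivor" & y == "survivor")
  c(roc_auc = roc_auc(y, score), metrics_from_confusion(tp, fp, fn, tn))
}

#' Cross-validated evaluation of a survival classifier
#'
#' Trains a C-support-vector classifier with a polynomial kernel on
#' repeated random train/test splits (200 splits of 75/25 by default) and
#' aggregates confusion-matrix metrics and the ROC AUC (from the
#' continuous decision score) as mean and SD across splits; additionally a
#' full-dataset fit-and-evaluate value is reported. Features are
#' standardized on the training split. Splits whose training or test set
#' contains a single class are skipped and counted. Deterministic under
#' \code{seed}.
#'
#' @param features list as returned by [build_features()].
#' @param n_splits number of random splits.
#' @param train_fraction fraction of patients in the training set.
#' @param seed integer seed (mandatory).
#' @param degree polynomial kernel degree.
#' @param cost regularization constant.
#' @return An object of class \code{icg_cohort_metrics}: \code{full}
#'   (full-dataset metrics), \code{cv_mean}, \code{cv_sd}, per-split table
#'   \code{cv}, skipped-split count and metadata.
#' @export
evaluate_classifier <- function(features, n_splits = 200,
                                train_fraction = 0.75, seed,
                                degree = 3, cost = 1) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  x <- features$x
  y <- features$y
  n <- nrow(x)
  stopifnot(n >= 20, nlevels(droplevels(y)) == 2)

  full_pred <- svm_predict(x, y, x, degree, cost)
  full <- classification_metrics(y, full_pred$class, full_pred$score)

  set.seed(seed)
  n_train <- round(train_fraction * n)
  per_split <- vector("list", n_splits)
  skipped <- 0L
  for (s in seq_len(n_splits)) {
    idx <- sample.int(n, n_train)
    y_tr <- y[idx]; y_te <- y[-idx]
    if (nlevels(droplevels(y_tr)) < 2 || nlevels(droplevels(y_te)) < 2) {
      skipped <- skipped + 1L
      next
    }
    pr <- svm_predict(x[idx, , drop = FALSE], y_tr,
                      x[-idx, , drop = FALSE], degree, cost)
    per_split[[s]] <- classification_metrics(y_te, pr$class, pr$score)
  }
  cv <- do.call(rbind, per_split)
  structure(list(
    model = features$model,
    full = full,
    cv_mean = colMeans(cv, na.rm = TRUE),
    cv_sd = apply(cv, 2, stats::sd, na.rm = TRUE),
    cv = as.data.frame(cv),
    n_splits = n_splits, n_skipped = skipped,
    train_fraction = train_fraction, seed = seed,
    degree = degree, cost = cost
  ), class = "icg_cohort_metrics")
}

#' @export
print.icg_cohort_metrics <- function(x, ...) {
  cat(sprintf("Survival classifier %s (positive class: non-survivor)\n",
              x$model))
  cat(sprintf("  %d/%d usable splits (train fraction %.2f, seed %d)\n",
              x$n_splits - x$n_skipped, x$n_splits, x$train_fraction,
              x$seed))
  tab <- rbind(full = x$full, cv_mean = x$cv_mean, cv_sd = x$cv_sd)
  print(round(tab, 3))
  invisible(x)
}

#' Metric dependence on a decision cutoff
#'
#' For a one-dimensional feature (e.g. the predicted postoperative R15),
#' classifies a patient as non-survivor whenever the feature is at or
#' above the cutoff, and reports the evaluation metrics per cutoff, both
#' on the full cohort and as mean/SD over random test subsets.
#'
#' @param feature numeric vector (one value per patient).
#' @param y label factor (levels \code{survivor}, \code{nonsurvivor}).
#' @param cutoffs cutoff grid.
#' @param n_splits,train_fraction,seed cross-validation settings; the test
#'   subset of each split is scored (thresholding needs no training).
#' @return data.frame with one row per cutoff: full-cohort metrics and
#'   their CV mean/SD.
#' @export
cutoff_scan <- function(feature, y, cutoffs = seq(0.05, 0.8, by = 0.05),
                        n_splits = 200, train_fraction = 0.75, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(length(feature) == length(y))
  n <- length(feature)
  metrics_at <- function(idx, theta) {
    pred <- factor(ifelse(feature[idx] >= theta, "nonsurvivor", "survivor"),
                   levels = levels(y))
    tp <- sum(pred == "nonsurvivor" & y[idx] == "nonsurvivor")
    fp <- sum(pred == "nonsurvivor" & y[idx] == "survivor")
    fn <- sum(pred == "survivor" & y[idx] == "nonsurvivor")
    tn <- sum(pred == "survivor" & y[idx] == "survivor")
    metrics_from_confusion(tp, fp, fn, tn)
  }
  set.seed(seed)
  test_sets <- replicate(n_splits,
                         setdiff(seq_len(n),
                                 sample.int(n, round(train_fraction * n))),
                         simplify = FALSE)
  rows <- lapply(cutoffs, function(theta) {
    full <- metrics_at(seq_len(n), theta)
    per <- do.call(rbind, lapply(test_sets, function(te) {
      if (nlevels(droplevels(y[te])) < 2) return(NULL)
      metrics_at(te, theta)
    }))
    data.frame(cutoff = theta, t(full),
               t(stats::setNames(colMeans(per, na.rm = TRUE),
                                 paste0("cv_mean_", colnames(per)))),
               t(stats::setNames(apply(per, 2, stats::sd, na.rm = TRUE),
                                 paste0("cv_sd_", colnames(per)))))
  })
  do.call(rbind, rows)
}
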