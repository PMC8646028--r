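#' Physiological body parameters
#'
#' Constructs the set of fixed whole-body parameters of the ICG model:
#' anthropometry, cardiac output, hematocrit, fractional organ volumes and
#' fractional blood flows. Defaults describe a 75 kg reference adult.
#'
#' ICG is confined to plasma (it is tightly bound to plasma proteins), so
#' every blood compartment contributes its volume times \code{1 - HCT} as
#' distribution space.
#'
#' @param BW body weight [kg].
#' @param HEIGHT body height [cm] (carried for reference; not used by the
#'   kinetic equations).
#' @param COBW cardiac output per body weight [ml/s/kg].
#' @param HCT hematocrit [-], fraction in (0, 1).
#' @param Fblood fraction of organ volume made up by blood vessels [-].
#' @param FVgi,FVli,FVlu,FVve,FVar,FVbi,FVpo,FVhv fractional tissue volumes
#'   [l/kg] of gastrointestinal tract, liver, lung, venous blood, arterial
#'   blood, bile, portal vein and hepatic vein.
#' @param FQgi fractional blood flow through the gastrointestinal tract
#'   (portal vein inflow) [-].
#' @param FQh fractional hepatic (hepatic-vein) blood flow [-]; must be at
#'   least \code{FQgi} so that the hepatic-artery fraction is non-negative.
#' @param Mr_icg molar mass of ICG [g/mole].
#' @param ti_icg injection duration of a bolus [s].
#' @param bil_plasma plasma bilirubin concentration [mM]; competitive
#'   inhibitor of hepatic ICG uptake. Default is the lower bound of the
#'   0.005--0.015 mM reference range, which reproduces healthy reference
#'   kinetics.
#'
#' @return An object of class \code{icg_body}, a named list of parameters.
#' @export
#' @examples
#' body <- body_parameters()
#' body$BW
body_parameters <- function(BW = 75, HEIGHT = 170, COBW = 0.83, HCT = 0.51,
                            Fblood = 0.02,
                            FVgi = 0.0171, FVli = 0.021, FVlu = 0.0297,
                            FVve = 0.0587, FVar = 0.0184, FVbi = 0.00071,
                            FVpo = 0.001, FVhv = 0.001,
                            FQgi = 0.19, FQh = 0.255,
                            Mr_icg = 774.96, ti_icg = 5,
                            bil_plasma = 0.005) {
  body <- list(BW = BW, HEIGHT = HEIGHT, COBW = COBW, HCT = HCT,
               Fblood = Fblood,
               FVgi = FVgi, FVli = FVli, FVlu = FVlu, FVve = FVve,
               FVar = FVar, FVbi = FVbi, FVpo = FVpo, FVhv = FVhv,
               FQgi = FQgi, FQh = FQh,
               Mr_icg = Mr_icg, ti_icg = ti_icg, bil_plasma = bil_plasma)
  class(body) <- "icg_body"
  validate_body(body)
  body
}

validate_body <- function(body) {
  vals <- unlist(body)
  if (any(!is.finite(vals)) || any(vals <= 0 & names(vals) != "bil_plasma")) {
    stop("invalid-parameter: all body parameters must be finite and positive",
         call. = FALSE)
  }
  if (body$bil_plasma < 0) {
    stop("invalid-parameter: bil_plasma must be non-negative", call. = FALSE)
  }
  for (nm in c("HCT", "Fblood", "FQgi", "FQh")) {
    if (body[[nm]] <= 0 || body[[nm]] >= 1) {
      stop(sprintf("invalid-parameter: %s must lie in (0, 1)", nm),
           call. = FALSE)
    }
  }
  if (body$FQh < body$FQgi) {
    stop("invalid-parameter: FQh must be >= FQgi (hepatic-artery fraction)",
         call. = FALSE)
  }
  invisible(body)
}

#' Hepatic transporter parameters
#'
#' Kinetic constants of the three consecutive hepatic transport steps:
#' sinusoidal uptake into the hepatocyte (OATP1B3-mediated, irreversible
#' Michaelis-Menten), canalicular excretion into bile (irreversible
#' Michaelis-Menten) and first-order transport from bile into feces.
#' Defaults are the calibrated reference values.
#'
#' @param ICGIM_Vmax maximal hepatic uptake rate [mmole/min per litre of
#'   liver tissue].
#' @param ICGIM_Km uptake affinity [mM].
#' @param ki_bil competitive bilirubin inhibition constant of uptake [mM].
#' @param ICGLI2CA_Vmax maximal biliary excretion rate [mmole/min/l liver].
#' @param ICGLI2CA_Km biliary excretion affinity [mM].
#' @param ICGLI2BI_k first-order bile-to-feces rate constant [1/min].
#' @param f_oatp1b3 dimensionless scaling factor of the uptake-transporter
#'   amount (1 = reference expression).
#'
#' @return An object of class \code{icg_transporters}.
#' @export
transporter_parameters <- function(ICGIM_Vmax = 0.037, ICGIM_Km = 0.0217,
                                   ki_bil = 0.02,
                                   ICGLI2CA_Vmax = 0.000944,
                                   ICGLI2CA_Km = 0.0124,
                                   ICGLI2BI_k = 0.000114,
                                   f_oatp1b3 = 1) {
  tp <- list(ICGIM_Vmax = ICGIM_Vmax, ICGIM_Km = ICGIM_Km, ki_bil = ki_bil,
             ICGLI2CA_Vmax = ICGLI2CA_Vmax, ICGLI2CA_Km = ICGLI2CA_Km,
             ICGLI2BI_k = ICGLI2BI_k, f_oatp1b3 = f_oatp1b3)
  class(tp) <- "icg_transporters"
  if (any(!is.finite(unlist(tp))) || any(unlist(tp) <= 0)) {
    stop("invalid-parameter: transporter parameters must be positive",
         call. = FALSE)
  }
  tp
}

#' Scenario parameters: cirrhosis, hepatectomy, flow scaling
#'
#' Disease and surgery scenarios are expressed as multiplicative
#' modifications of the healthy reference model:
#' \describe{
#'   \item{f_shunts}{fraction of hepatic (arterial + portal) blood routed
#'     through intrahepatic shunts directly into the hepatic vein, bypassing
#'     the liver tissue, in [0, 1).}
#'   \item{f_tissue_loss}{fraction of functional parenchymal volume lost
#'     (scarring/necrosis in cirrhosis), in [0, 1).}
#'   \item{resection_rate}{fraction of the liver volume surgically removed,
#'     in [0, 0.9]; removes tissue together with its vessels.}
#'   \item{f_bloodflow}{scaling of hepatic blood flow (used for trial
#'     clamping); the flow difference is rerouted to the rest compartment so
#'     cardiac output is preserved.}
#'   \item{f_cardiac_output}{scaling of cardiac output.}
#' }
#'
#' @param f_shunts,f_tissue_loss,resection_rate,f_bloodflow,f_cardiac_output
#'   see Details.
#' @return An object of class \code{icg_scenario}.
#' @seealso [cirrhosis_scenario()] for the coupled cirrhosis degree.
#' @export
scenario_parameters <- function(f_shunts = 0, f_tissue_loss = 0,
                                resection_rate = 0, f_bloodflow = 1,
                                f_cardiac_output = 1) {
  sc <- list(f_shunts = f_shunts, f_tissue_loss = f_tissue_loss,
             resection_rate = resection_rate, f_bloodflow = f_bloodflow,
             f_cardiac_output = f_cardiac_output)
  class(sc) <- "icg_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (any(!is.finite(unlist(sc)))) {
    stop("invalid-parameter: scenario parameters must be finite", call. = FALSE)
  }
  if (sc$f_shunts < 0 || sc$f_shunts >= 1) {
    stop("invalid-parameter: f_shunts must lie in [0, 1)", call. = FALSE)
  }
  if (sc$f_tissue_loss < 0 || sc$f_tissue_loss >= 1) {
    stop("invalid-parameter: f_tissue_loss must lie in [0, 1)", call. = FALSE)
  }
  if (sc$resection_rate < 0 || sc$resection_rate > 0.9) {
    stop("invalid-parameter: resection_rate must lie in [0, 0.9]",
         call. = FALSE)
  }
  if (sc$f_bloodflow <= 0 || sc$f_cardiac_output <= 0) {
    stop("invalid-parameter: flow scalings must be positive", call. = FALSE)
  }
  invisible(sc)
}

#' Cirrhosis scenario with coupled shunting and tissue loss
#'
#' The composite cirrhosis degree varies intrahepatic shunting and
#' functional tissue loss in lockstep: \code{f_shunts = f_tissue_loss =
#' f_cirrhosis}. Standard degrees used for the Child-Turcotte-Pugh classes
#' are available through [ctp_mapping()].
#'
#' @param f_cirrhosis cirrhosis degree in [0, 1); 0 = healthy.
#' @param ... further arguments passed to [scenario_parameters()]
#'   (e.g. \code{resection_rate}).
#' @return An \code{icg_scenario}.
#' @export
#' @examples
#' cirrhosis_scenario(0.41)  # mild cirrhosis (CTP-A)
cirrhosis_scenario <- function(f_cirrhosis = 0, ...) {
  scenario_parameters(f_shunts = f_cirrhosis, f_tissue_loss = f_cirrhosis,
                      ...)
}

#' Bundle of all model parameters
#'
#' @param body an \code{icg_body}, see [body_parameters()].
#' @param transporters an \code{icg_transporters},
#'   see [transporter_parameters()].
#' @return An object of class \code{icg_parameters}.
#' @export
icg_parameters <- function(body = body_parameters(),
                           transporters = transporter_parameters()) {
  stopifnot(inherits(body, "icg_body"),
            inherits(transporters, "icg_transporters"))
  structure(list(body = body, transporters = transporters),
            class = "icg_parameters")
}

# flat serialization keys use the LI__ prefix for hepatic kinetic constants
transporter_key <- function(nm) {
  paste0("LI__", sub("^ki_bil$", "ICGIM_ki_bil", nm))
}

#' Serialize parameters to a flat key-value list
#'
#' Hepatic kinetic constants carry the liver prefix (\code{LI__ICGIM_Vmax},
#' \code{LI__ICGIM_Km}, ...); body and scenario parameters use their plain
#' symbols (\code{FVli}, \code{f_shunts}, ...). The flat list round-trips
#' through YAML or JSON configuration files.
#'
#' @param params an \code{icg_parameters} bundle.
#' @param scenario optional \code{icg_scenario} to include.
#' @return Named list of numeric scalars.
#' @export
params_to_list <- function(params, scenario = NULL) {
  out <- as.list(unclass(params$body))
  tp <- unclass(params$transporters)
  names(tp) <- vapply(names(tp), transporter_key, "")
  out <- c(out, tp)
  if (!is.null(scenario)) out <- c(out, as.list(unclass(scenario)))
  out
}

#' Build parameters from a flat key-value list
#'
#' Inverse of [params_to_list()]. Unknown keys are rejected so that typos in
#' configuration files surface immediately.
#'
#' @param x named list (e.g. parsed from YAML/JSON).
#' @return List with elements \code{params} (\code{icg_parameters}) and
#'   \code{scenario} (\code{icg_scenario}).
#' @export
params_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)))
  body_nm <- names(formals(body_parameters))
  tp_nm <- names(formals(transporter_parameters))
  sc_nm <- names(formals(scenario_parameters))
  tp_keys <- vapply(tp_nm, transporter_key, "")
  known <- c(body_nm, tp_keys, sc_nm)
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1L,
                          TRUE)]
  if (length(bad)) {
    stop("parameter values must be numeric scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  body <- do.call(body_parameters, x[intersect(names(x), body_nm)])
  tp_args <- x[intersect(names(x), tp_keys)]
  names(tp_args) <- tp_nm[match(names(tp_args), tp_keys)]
  tp <- do.call(transporter_parameters, tp_args)
  sc <- do.call(scenario_parameters, x[intersect(names(x), sc_nm)])
  list(params = icg_parameters(body, tp), scenario = sc)
}

#' @export
print.icg_parameters <- function(x, ...) {
  cat("ICG PBPK parameter set\n")
  cat(sprintf("  body: BW %.1f kg, cardiac output %.3f l/min, HCT %.2f\n",
              x$body$BW, x$body$COBW / 1000 * x$body$BW * 60, x$body$HCT))
  tp <- x$transporters
  cat(sprintf("  uptake: Vmax %.4g mmole/min/l, Km %.4g mM (f_oatp1b3 %.2f)\n",
              tp$ICGIM_Vmax, tp$ICGIM_Km, tp$f_oatp1b3))
  cat(sprintf("  bile:   Vmax %.4g mmole/min/l, Km %.4g mM, k_feces %.4g 1/min\n",
              tp$ICGLI2CA_Vmax, tp$ICGLI2CA_Km, tp$ICGLI2BI_k))
  invisible(x)
}

#' Convert an ICG mass to molar amount
#'
#' @param mg mass [mg].
#' @param Mr_icg molar mass [g/mole].
#' @return Amount in mmole.
#' @export
mg_to_mmole <- function(mg, Mr_icg = 774.96) mg / Mr_icg
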