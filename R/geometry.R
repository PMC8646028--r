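#' Derive compartment volumes and blood flows
#'
#' Computes the physical geometry of the circulation from the body
#' parameters and the scenario: blood and plasma volumes of every
#' compartment, liver tissue volume, and the blood-flow network.
#'
#' Flow conservation holds by construction: cardiac output equals lung flow
#' and splits into the hepatic and rest paths (\code{Q_co = Q_lu = Q_h +
#' Q_re}), and hepatic-vein outflow equals hepatic-artery plus portal inflow
#' (\code{Q_h = Q_ha + Q_po}). Trial clamping (\code{f_bloodflow < 1})
#' rescales \code{Q_h} with the difference rerouted to the rest compartment,
#' preserving cardiac output. The shunted fraction \code{f_shunts} applies
#' equally to the hepatic-artery and portal streams.
#'
#' Volumes: big-vessel compartments (venous, arterial, portal, hepatic vein)
#' occupy \code{FV * BW}; organ blood spaces occupy \code{FV * BW * Fblood};
#' the rest compartment closes the volume budget, its blood space being
#' \code{Fblood} times the body volume not covered by the explicit organs
#' (body density 1 kg/l). Functional liver tissue volume is
#' \code{FVli * BW * (1 - Fblood) * (1 - f_tissue_loss) *
#' (1 - resection_rate)}; resection additionally removes the corresponding
#' liver vessels, cirrhotic tissue loss does not.
#'
#' @param body an \code{icg_body}.
#' @param scenario an \code{icg_scenario}.
#' @return An object of class \code{icg_geometry} with elements
#'   \code{V_blood}, \code{V_plasma} (named vectors, litres),
#'   \code{V_li_tissue}, \code{V_bile} (litres), flows \code{Q_co},
#'   \code{Q_lu}, \code{Q_h}, \code{Q_ha}, \code{Q_po}, \code{Q_re},
#'   \code{Q_shunt} (l/min) and the functional liver fraction
#'   \code{f_functional}.
#' @export
#' @examples
#' geo <- derive_geometry(body_parameters(), scenario_parameters())
#' geo$Q_co   # 3.735 l/min for the 75 kg reference
derive_geometry <- function(body = body_parameters(),
                            scenario = scenario_parameters()) {
  validate_body(body)
  validate_scenario(scenario)

  BW <- body$BW
  fv_sum <- body$FVgi + body$FVli + body$FVlu + body$FVve + body$FVar +
    body$FVbi + body$FVpo + body$FVhv
  if (fv_sum >= 1) {
    stop("invalid-parameter: fractional volumes exceed body volume",
         call. = FALSE)
  }
  rr <- scenario$resection_rate
  V_blood <- c(
    ve = body$FVve * BW,
    ar = body$FVar * BW,
    po = body$FVpo * BW,
    hv = body$FVhv * BW,
    lu = body$FVlu * BW * body$Fblood,
    gi = body$FVgi * BW * body$Fblood,
    li = body$FVli * BW * body$Fblood * (1 - rr),
    re = body$Fblood * BW * (1 - fv_sum)
  )
  V_plasma <- V_blood * (1 - body$HCT)
  V_li_tissue <- body$FVli * BW * (1 - body$Fblood) *
    (1 - scenario$f_tissue_loss) * (1 - rr)
  V_bile <- body$FVbi * BW

  # cardiac output: ml/s/kg -> l/min
  Q_co <- body$COBW / 1000 * BW * 60 * scenario$f_cardiac_output
  Q_h <- body$FQh * Q_co * scenario$f_bloodflow
  Q_po <- body$FQgi * Q_co * scenario$f_bloodflow
  Q_ha <- Q_h - Q_po
  Q_re <- Q_co - Q_h
  if (Q_re < 0) {
    stop("invalid-parameter: hepatic flow exceeds cardiac output",
         call. = FALSE)
  }
  geo <- list(
    V_blood = V_blood, V_plasma = V_plasma,
    V_li_tissue = V_li_tissue, V_bile = V_bile,
    Q_co = Q_co, Q_lu = Q_co, Q_h = Q_h, Q_ha = Q_ha, Q_po = Q_po,
    Q_re = Q_re,
    Q_shunt = scenario$f_shunts * Q_h,
    f_shunts = scenario$f_shunts,
    f_functional = (1 - scenario$f_tissue_loss) * (1 - rr)
  )
  class(geo) <- "icg_geometry"
  geo
}

#' @export
print.icg_geometry <- function(x, ...) {
  cat("ICG circulation geometry\n")
  cat(sprintf("  cardiac output %.4f l/min; hepatic %.4f (arterial %.4f + portal %.4f), rest %.4f\n",
              x$Q_co, x$Q_h, x$Q_ha, x$Q_po, x$Q_re))
  cat(sprintf("  shunted hepatic flow %.4f l/min (f_shunts %.2f)\n",
              x$Q_shunt, x$f_shunts))
  cat(sprintf("  liver tissue %.4f l; total plasma %.3f l\n",
              x$V_li_tissue, sum(x$V_plasma)))
  invisible(x)
}
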