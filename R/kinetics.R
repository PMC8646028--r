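#' Hepatic ICG uptake rate
#'
#' Irreversible Michaelis-Menten uptake of ICG from the liver plasma space
#' into the hepatocytes, scaled by functional liver tissue volume and the
#' transport-protein amount, with competitive inhibition by plasma
#' bilirubin (bilirubin and ICG share the sinusoidal uptake transporter):
#' \deqn{v = f_{oatp1b3} \cdot V_{max} \cdot V_{li} \cdot
#'   \frac{c}{K_m (1 + bil/k_{i,bil}) + c}}
#'
#' @param c_liver_plasma ICG concentration in liver plasma [mM].
#' @param tp an \code{icg_transporters}.
#' @param v_liver_tissue functional liver tissue volume [l].
#' @param bil plasma bilirubin concentration [mM].
#' @return Uptake rate [mmole/min].
#' @export
uptake_rate <- function(c_liver_plasma, tp, v_liver_tissue, bil = 0.005) {
  stopifnot(c_liver_plasma >= 0, v_liver_tissue >= 0, bil >= 0)
  km_app <- tp$ICGIM_Km * (1 + bil / tp$ki_bil)
  tp$f_oatp1b3 * tp$ICGIM_Vmax * v_liver_tissue *
    c_liver_plasma / (km_app + c_liver_plasma)
}

#' Biliary ICG excretion rate
#'
#' Irreversible Michaelis-Menten excretion of hepatocellular ICG into the
#' bile canaliculi, scaled by functional liver tissue volume.
#'
#' @param c_liver_tissue ICG concentration in liver tissue [mM].
#' @param tp an \code{icg_transporters}.
#' @param v_liver_tissue functional liver tissue volume [l].
#' @return Excretion rate [mmole/min].
#' @export
biliary_excretion_rate <- function(c_liver_tissue, tp, v_liver_tissue) {
  stopifnot(c_liver_tissue >= 0, v_liver_tissue >= 0)
  tp$ICGLI2CA_Vmax * v_liver_tissue *
    c_liver_tissue / (tp$ICGLI2CA_Km + c_liver_tissue)
}

#' Bile-to-feces transport rate
#'
#' First-order transport of ICG from the bile into the feces. Like the
#' carrier-mediated steps it scales with the functional liver fraction
#' \code{(1 - f_tissue_loss) * (1 - resection_rate)}.
#'
#' @param bile_amount ICG amount in bile [mmole].
#' @param tp an \code{icg_transporters}.
#' @param f_functional functional liver fraction [-].
#' @return Transport rate [mmole/min].
#' @export
feces_transport_rate <- function(bile_amount, tp, f_functional = 1) {
  stopifnot(bile_amount >= 0, f_functional >= 0)
  tp$ICGLI2BI_k * f_functional * bile_amount
}

# state ordering of the ODE system (amounts in mmole)
STATE_NAMES <- c("ve", "ar", "lu", "gi", "po", "li", "hv", "re",
                 "li_tissue", "bile", "feces", "administered")

#' Right-hand side of the ICG PBPK ODE system
#'
#' The state carries ICG amounts [mmole] in the plasma spaces of the venous,
#' arterial, lung, gastrointestinal, portal-vein, liver, hepatic-vein and
#' rest blood compartments, the liver tissue and the bile, plus the
#' cumulative feces and cumulative administered amounts.
#'
#' Blood transport between compartments is irreversible and convective:
#' the flux out of compartment \emph{i} is \code{Q_i * C_i} with \code{C_i}
#' the plasma concentration of the source compartment. The shunted fraction
#' of the arterial and portal streams merges directly into the hepatic-vein
#' compartment. Dosing enters the venous plasma. The sum of all state
#' derivatives other than the administered-amount bookkeeping equals the
#' input rate exactly, so total system amount plus feces tracks the
#' administered amount (mass balance by construction).
#'
#' @param t time [min].
#' @param state named or ordered numeric vector of amounts [mmole]; order
#'   \code{ve, ar, lu, gi, po, li, hv, re, li_tissue, bile, feces,
#'   administered}.
#' @param params an \code{icg_parameters}.
#' @param geometry an \code{icg_geometry} (precomputed once per simulation).
#' @param input_rate function of time returning the dosing rate [mmole/min].
#' @return List with the derivative vector, as expected by
#'   \code{deSolve} integrators.
#' @export
icg_rhs <- function(t, state, params, geometry, input_rate = function(t) 0) {
  if (any(!is.finite(state))) {
    stop("non-finite state encountered at t = ", t, call. = FALSE)
  }
  Vp <- geometry$V_plasma
  # negative excursions from the integrator are clipped for the kinetic laws
  s <- pmax(as.numeric(state), 0)
  cve <- s[1L] / Vp[["ve"]]; car <- s[2L] / Vp[["ar"]]
  clu <- s[3L] / Vp[["lu"]]; cgi <- s[4L] / Vp[["gi"]]
  cpo <- s[5L] / Vp[["po"]]; cli <- s[6L] / Vp[["li"]]
  chv <- s[7L] / Vp[["hv"]]; cre <- s[8L] / Vp[["re"]]
  cli_t <- if (geometry$V_li_tissue > 0) s[9L] / geometry$V_li_tissue else 0

  fs <- geometry$f_shunts
  v_ve_lu <- geometry$Q_co * cve
  v_lu_ar <- geometry$Q_co * clu
  v_ar_gi <- geometry$Q_po * car
  v_gi_po <- geometry$Q_po * cgi
  v_po_li <- (1 - fs) * geometry$Q_po * cpo
  v_po_hv <- fs * geometry$Q_po * cpo
  v_ar_li <- (1 - fs) * geometry$Q_ha * car
  v_ar_hv <- fs * geometry$Q_ha * car
  v_li_hv <- (1 - fs) * geometry$Q_h * cli
  v_hv_ve <- geometry$Q_h * chv
  v_ar_re <- geometry$Q_re * car
  v_re_ve <- geometry$Q_re * cre

  tp <- params$transporters
  v_up <- uptake_rate(cli, tp, geometry$V_li_tissue, params$body$bil_plasma)
  v_bi <- biliary_excretion_rate(cli_t, tp, geometry$V_li_tissue)
  v_fe <- feces_transport_rate(s[10L], tp, geometry$f_functional)

  inp <- input_rate(t)
  list(c(
    ve           = inp + v_hv_ve + v_re_ve - v_ve_lu,
    ar           = v_lu_ar - v_ar_gi - v_ar_li - v_ar_hv - v_ar_re,
    lu           = v_ve_lu - v_lu_ar,
    gi           = v_ar_gi - v_gi_po,
    po           = v_gi_po - v_po_li - v_po_hv,
    li           = v_po_li + v_ar_li - v_li_hv - v_up,
    hv           = v_li_hv + v_po_hv + v_ar_hv - v_hv_ve,
    re           = v_ar_re - v_re_ve,
    li_tissue    = v_up - v_bi,
    bile         = v_bi - v_fe,
    feces        = v_fe,
    administered = inp
  ))
}
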