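# Rate laws of the metabolic network. Every reversible reaction is split
# into non-negative forward/backward parts carried as separate registry
# labels; the ATP-equation labels 54-65 are the base rates multiplied by the
# adenylate closure factors S1/S2 so the stoichiometry stays state
# independent. rate_system() evaluates the full rate vector and, on request,
# the K x N matrix of analytic rate gradients used to assemble Jacobians.

# carrier-mediated transport, one direction: Tmax * x / (x + K)
.tr <- function(x, Tmax, K) Tmax * x / (x + K)
.dtr <- function(x, Tmax, K) Tmax * K / (x + K)^2

#' Evaluate all reaction and transport rates (and gradients)
#'
#' @param state Named numeric state vector in [state_names()] order.
#' @param params Parameter list from [default_parameters()].
#' @param t Time (s); determines the stimulation inputs and the CBF.
#' @param protocol Protocol from [activation_protocol()].
#' @param gradients If `TRUE`, also return the K x N matrix of partial
#'   derivatives of each rate with respect to each state variable.
#' @return List with `R` (named rate vector, mM/s in the compartment of
#'   definition) and, if requested, `dR` (K x N matrix).
#' @export
rate_system <- function(state, params, t, protocol, gradients = FALSE) {
  p <- params
  s <- as.numeric(state)
  names(s) <- state_names()
  if (any(s[setdiff(state_names(), "Vv")] < 0)) {
    stop("negative concentration: ",
         paste(state_names()[s < 0], collapse = ", "))
  }
  labs <- reaction_labels()
  R <- stats::setNames(numeric(length(labs)), labs)
  dR <- NULL
  if (gradients) {
    dR <- matrix(0, length(labs), 29, dimnames = list(labs, state_names()))
  }
  Ntot <- p$N_tot; Ctot <- p$C_tot

  ADPn <- adp_from_atp(s["ATP_n"], p); dADPn <- dadp_datp(s["ATP_n"], p)
  ADPg <- adp_from_atp(s["ATP_g"], p); dADPg <- dadp_datp(s["ATP_g"], p)
  S1 <- amp_closure_factor(s["ATP_n"], p); dS1 <- damp_closure_factor(s["ATP_n"], p)
  S2 <- amp_closure_factor(s["ATP_g"], p); dS2 <- damp_closure_factor(s["ATP_g"], p)

  Fv <- cbf_profile(t, protocol)
  stim <- stimulation_inputs(t, protocol)

  ## -- sodium leak and pump --------------------------------------------
  R["1"] <- p$SmVn * p$gNa_n / p$Faraday *
    (p$RTF * log(p$Na_e / s["Na_n"]) - p$psi_n)
  R["2"] <- p$SmVg * p$gNa_g / p$Faraday *
    (p$RTF * log(p$Na_e / s["Na_g"]) - p$psi_g)
  hpn <- 1 / (1 + s["ATP_n"] / p$Km_pump)
  hpg <- 1 / (1 + s["ATP_g"] / p$Km_pump)
  R["3"] <- p$SmVn * p$kpump_n * s["ATP_n"] * s["Na_n"] * hpn
  R["4"] <- p$SmVg * p$kpump_g * s["ATP_g"] * s["Na_g"] * hpg

  ## -- glucose transport ------------------------------------------------
  R["5f"] <- .tr(s["GLC_e"], p$Tmax_GLC_en, p$Kt_GLC_en)
  R["5b"] <- .tr(s["GLC_n"], p$Tmax_GLC_en, p$Kt_GLC_en)
  R["6f"] <- .tr(s["GLC_e"], p$Tmax_GLC_eg, p$Kt_GLC_eg)
  R["6b"] <- .tr(s["GLC_g"], p$Tmax_GLC_eg, p$Kt_GLC_eg)
  R["7f"] <- .tr(s["GLC_c"], p$Tmax_GLC_cg, p$Kt_GLC_cg)
  R["7b"] <- .tr(s["GLC_g"], p$Tmax_GLC_cg, p$Kt_GLC_cg)
  R["8f"] <- .tr(s["GLC_c"], p$Tmax_GLC_ce, p$Kt_GLC_ce)
  R["8b"] <- .tr(s["GLC_e"], p$Tmax_GLC_ce, p$Kt_GLC_ce)

  ## -- glycolysis --------------------------------------------------------
  phin <- 1 / (1 + (s["ATP_n"] / p$KI_ATP)^p$nH)
  phig <- 1 / (1 + (s["ATP_g"] / p$KI_ATP)^p$nH)
  R["9"] <- p$kHKPFK_n * s["ATP_n"] * s["GLC_n"] / (s["GLC_n"] + p$Kg) * phin
  R["10"] <- p$kHKPFK_g * s["ATP_g"] * s["GLC_g"] / (s["GLC_g"] + p$Kg) * phig
  ncn <- s["NADHcyto_n"]; ncg <- s["NADHcyto_g"]
  R["11"] <- p$kPGK_n * s["GAP_n"] * ADPn * (Ntot - ncn) / ncn
  R["12"] <- p$kPGK_g * s["GAP_g"] * ADPg * (Ntot - ncg) / ncg
  R["13"] <- p$kPK_n * s["PEP_n"] * ADPn
  R["14"] <- p$kPK_g * s["PEP_g"] * ADPg
  R["15f"] <- p$kLDHp_n * s["PYR_n"] * ncn
  R["15b"] <- p$kLDHm_n * s["LAC_n"] * (Ntot - ncn)
  R["16f"] <- p$kLDHp_g * s["PYR_g"] * ncg
  R["16b"] <- p$kLDHm_g * s["LAC_g"] * (Ntot - ncg)

  ## -- lactate transport -------------------------------------------------
  R["17f"] <- .tr(s["LAC_n"], p$Tmax_LAC_ne, p$Kt_LAC_ne)
  R["17b"] <- .tr(s["LAC_e"], p$Tmax_LAC_ne, p$Kt_LAC_ne)
  R["18f"] <- .tr(s["LAC_g"], p$Tmax_LAC_ge, p$Kt_LAC_ge)
  R["18b"] <- .tr(s["LAC_e"], p$Tmax_LAC_ge, p$Kt_LAC_ge)
  R["19f"] <- .tr(s["LAC_g"], p$Tmax_LAC_gc, p$Kt_LAC_gc)
  R["19b"] <- .tr(s["LAC_c"], p$Tmax_LAC_gc, p$Kt_LAC_gc)
  R["20f"] <- .tr(s["LAC_e"], p$Tmax_LAC_ec, p$Kt_LAC_ec)
  R["20b"] <- .tr(s["LAC_c"], p$Tmax_LAC_ec, p$Kt_LAC_ec)

  ## -- mitochondrial metabolism ------------------------------------------
  nmn <- s["NADHmito_n"]; nmg <- s["NADHmito_g"]
  qn <- (Ntot - nmn) / (Ntot - nmn + p$Km_NAD_n)
  qg <- (Ntot - nmg) / (Ntot - nmg + p$Km_NAD_g)
  R["21"] <- p$Vmax_in_n * s["PYR_n"] / (s["PYR_n"] + p$Km_mito) * qn
  R["23"] <- p$Vmax_in_g * s["PYR_g"] / (s["PYR_g"] + p$Km_mito) * qg
  o2n <- s["O2_n"] / (s["O2_n"] + p$KO2_mito)
  o2g <- s["O2_g"] / (s["O2_g"] + p$KO2_mito)
  adn <- ADPn / (ADPn + p$Km_ADP_n)
  adg <- ADPg / (ADPg + p$Km_ADP_g)
  nhn <- nmn / (nmn + p$Km_NADH_n)
  nhg <- nmg / (nmg + p$Km_NADH_g)
  R["22"] <- p$Vmax_out_n * o2n * adn * nhn
  R["24"] <- p$Vmax_out_g * o2g * adg * nhg

  ## -- NADH shuttles -----------------------------------------------------
  Rmn <- ncn / (Ntot - ncn); Rpn <- (Ntot - nmn) / nmn
  Rmg <- ncg / (Ntot - ncg); Rpg <- (Ntot - nmg) / nmg
  fmn <- Rmn / (Rmn + p$Mcyto_n); fpn <- Rpn / (Rpn + p$Mmito_n)
  fmg <- Rmg / (Rmg + p$Mcyto_g); fpg <- Rpg / (Rpg + p$Mmito_g)
  R["25"] <- p$TNADH_n * fmn * fpn
  R["26"] <- p$TNADH_g * fmg * fpg

  ## -- creatine kinase ---------------------------------------------------
  R["27f"] <- p$kCKp_n * ADPn * s["PCr_n"]
  R["27b"] <- p$kCKm_n * s["ATP_n"] * (Ctot - s["PCr_n"])
  R["28f"] <- p$kCKp_g * ADPg * s["PCr_g"]
  R["28b"] <- p$kCKm_g * s["ATP_g"] * (Ctot - s["PCr_g"])

  ## -- oxygen and capillary exchange -------------------------------------
  yc <- p$HbOP / s["O2_c"] - 1
  O2cap <- p$KO2 * yc^(-1 / p$nh_O2)
  R["29"] <- p$PScapVn * (O2cap - s["O2_n"])
  R["30"] <- p$PScapVg * (O2cap - s["O2_g"])
  R["31"] <- 2 * Fv / p$Vcap * (p$O2_a - s["O2_c"])
  R["32"] <- 2 * Fv / p$Vcap * (p$GLC_a - s["GLC_c"])
  R["33"] <- 2 * Fv / p$Vcap * (p$LAC_a - s["LAC_c"])

  ## -- ATPase offsets ----------------------------------------------------
  R["34"] <- S1 * p$JATPases_n
  R["35"] <- S2 * p$JATPases_g
  R["36"] <- S2 * p$Jpump0_g

  ## -- venous balloon and deoxyhemoglobin --------------------------------
  vo <- venous_outflow(s["Vv"], Fv, p)
  R["37"] <- vo$dVv
  R["38"] <- 2 * Fv * (p$O2_a - s["O2_c"])
  R["39"] <- vo$Fout * s["dHb"] / s["Vv"]

  ## -- stimulation -------------------------------------------------------
  R["40"] <- stim[[1]]
  R["41"] <- stim[[2]]

  ## -- ATP-equation rates (closure-scaled copies) ------------------------
  R["54"] <- S1 * R["9"];   R["55"] <- S2 * R["10"]
  R["56"] <- S1 * R["11"];  R["57"] <- S2 * R["12"]
  R["58"] <- S1 * R["13"];  R["59"] <- S2 * R["14"]
  R["60"] <- S1 * R["3"];   R["61"] <- S2 * R["4"]
  R["62"] <- S1 * R["22"];  R["63"] <- S2 * R["24"]
  R["64f"] <- S1 * R["27f"]; R["64b"] <- S1 * R["27b"]
  R["65f"] <- S2 * R["28f"]; R["65b"] <- S2 * R["28b"]

  if (!gradients) return(list(R = R))

  ## ---- analytic gradients ----------------------------------------------
  dR["1", "Na_n"] <- -p$SmVn * p$gNa_n / p$Faraday * p$RTF / s["Na_n"]
  dR["2", "Na_g"] <- -p$SmVg * p$gNa_g / p$Faraday * p$RTF / s["Na_g"]
  dR["3", "Na_n"] <- p$SmVn * p$kpump_n * s["ATP_n"] * hpn
  dR["3", "ATP_n"] <- p$SmVn * p$kpump_n * s["Na_n"] *
    (hpn - s["ATP_n"] * hpn^2 / p$Km_pump)
  dR["4", "Na_g"] <- p$SmVg * p$kpump_g * s["ATP_g"] * hpg
  dR["4", "ATP_g"] <- p$SmVg * p$kpump_g * s["Na_g"] *
    (hpg - s["ATP_g"] * hpg^2 / p$Km_pump)

  dR["5f", "GLC_e"] <- .dtr(s["GLC_e"], p$Tmax_GLC_en, p$Kt_GLC_en)
  dR["5b", "GLC_n"] <- .dtr(s["GLC_n"], p$Tmax_GLC_en, p$Kt_GLC_en)
  dR["6f", "GLC_e"] <- .dtr(s["GLC_e"], p$Tmax_GLC_eg, p$Kt_GLC_eg)
  dR["6b", "GLC_g"] <- .dtr(s["GLC_g"], p$Tmax_GLC_eg, p$Kt_GLC_eg)
  dR["7f", "GLC_c"] <- .dtr(s["GLC_c"], p$Tmax_GLC_cg, p$Kt_GLC_cg)
  dR["7b", "GLC_g"] <- .dtr(s["GLC_g"], p$Tmax_GLC_cg, p$Kt_GLC_cg)
  dR["8f", "GLC_c"] <- .dtr(s["GLC_c"], p$Tmax_GLC_ce, p$Kt_GLC_ce)
  dR["8b", "GLC_e"] <- .dtr(s["GLC_e"], p$Tmax_GLC_ce, p$Kt_GLC_ce)

  dphin <- -p$nH * (s["ATP_n"] / p$KI_ATP)^(p$nH - 1) / p$KI_ATP * phin^2
  dphig <- -p$nH * (s["ATP_g"] / p$KI_ATP)^(p$nH - 1) / p$KI_ATP * phig^2
  dR["9", "GLC_n"] <- p$kHKPFK_n * s["ATP_n"] * phin *
    p$Kg / (s["GLC_n"] + p$Kg)^2
  dR["9", "ATP_n"] <- p$kHKPFK_n * s["GLC_n"] / (s["GLC_n"] + p$Kg) *
    (phin + s["ATP_n"] * dphin)
  dR["10", "GLC_g"] <- p$kHKPFK_g * s["ATP_g"] * phig *
    p$Kg / (s["GLC_g"] + p$Kg)^2
  dR["10", "ATP_g"] <- p$kHKPFK_g * s["GLC_g"] / (s["GLC_g"] + p$Kg) *
    (phig + s["ATP_g"] * dphig)

  ratn <- (Ntot - ncn) / ncn; ratg <- (Ntot - ncg) / ncg
  dR["11", "GAP_n"] <- p$kPGK_n * ADPn * ratn
  dR["11", "ATP_n"] <- p$kPGK_n * s["GAP_n"] * dADPn * ratn
  dR["11", "NADHcyto_n"] <- -p$kPGK_n * s["GAP_n"] * ADPn * Ntot / ncn^2
  dR["12", "GAP_g"] <- p$kPGK_g * ADPg * ratg
  dR["12", "ATP_g"] <- p$kPGK_g * s["GAP_g"] * dADPg * ratg
  dR["12", "NADHcyto_g"] <- -p$kPGK_g * s["GAP_g"] * ADPg * Ntot / ncg^2
  dR["13", "PEP_n"] <- p$kPK_n * ADPn
  dR["13", "ATP_n"] <- p$kPK_n * s["PEP_n"] * dADPn
  dR["14", "PEP_g"] <- p$kPK_g * ADPg
  dR["14", "ATP_g"] <- p$kPK_g * s["PEP_g"] * dADPg

  dR["15f", "PYR_n"] <- p$kLDHp_n * ncn
  dR["15f", "NADHcyto_n"] <- p$kLDHp_n * s["PYR_n"]
  dR["15b", "LAC_n"] <- p$kLDHm_n * (Ntot - ncn)
  dR["15b", "NADHcyto_n"] <- -p$kLDHm_n * s["LAC_n"]
  dR["16f", "PYR_g"] <- p$kLDHp_g * ncg
  dR["16f", "NADHcyto_g"] <- p$kLDHp_g * s["PYR_g"]
  dR["16b", "LAC_g"] <- p$kLDHm_g * (Ntot - ncg)
  dR["16b", "NADHcyto_g"] <- -p$kLDHm_g * s["LAC_g"]

  dR["17f", "LAC_n"] <- .dtr(s["LAC_n"], p$Tmax_LAC_ne, p$Kt_LAC_ne)
  dR["17b", "LAC_e"] <- .dtr(s["LAC_e"], p$Tmax_LAC_ne, p$Kt_LAC_ne)
  dR["18f", "LAC_g"] <- .dtr(s["LAC_g"], p$Tmax_LAC_ge, p$Kt_LAC_ge)
  dR["18b", "LAC_e"] <- .dtr(s["LAC_e"], p$Tmax_LAC_ge, p$Kt_LAC_ge)
  dR["19f", "LAC_g"] <- .dtr(s["LAC_g"], p$Tmax_LAC_gc, p$Kt_LAC_gc)
  dR["19b", "LAC_c"] <- .dtr(s["LAC_c"], p$Tmax_LAC_gc, p$Kt_LAC_gc)
  dR["20f", "LAC_e"] <- .dtr(s["LAC_e"], p$Tmax_LAC_ec, p$Kt_LAC_ec)
  dR["20b", "LAC_c"] <- .dtr(s["LAC_c"], p$Tmax_LAC_ec, p$Kt_LAC_ec)

  dR["21", "PYR_n"] <- p$Vmax_in_n * qn * p$Km_mito / (s["PYR_n"] + p$Km_mito)^2
  dR["21", "NADHmito_n"] <- -p$Vmax_in_n * s["PYR_n"] / (s["PYR_n"] + p$Km_mito) *
    p$Km_NAD_n / (Ntot - nmn + p$Km_NAD_n)^2
  dR["23", "PYR_g"] <- p$Vmax_in_g * qg * p$Km_mito / (s["PYR_g"] + p$Km_mito)^2
  dR["23", "NADHmito_g"] <- -p$Vmax_in_g * s["PYR_g"] / (s["PYR_g"] + p$Km_mito) *
    p$Km_NAD_g / (Ntot - nmg + p$Km_NAD_g)^2

  dR["22", "O2_n"] <- p$Vmax_out_n * adn * nhn *
    p$KO2_mito / (s["O2_n"] + p$KO2_mito)^2
  dR["22", "ATP_n"] <- p$Vmax_out_n * o2n * nhn *
    p$Km_ADP_n / (ADPn + p$Km_ADP_n)^2 * dADPn
  dR["22", "NADHmito_n"] <- p$Vmax_out_n * o2n * adn *
    p$Km_NADH_n / (nmn + p$Km_NADH_n)^2
  dR["24", "O2_g"] <- p$Vmax_out_g * adg * nhg *
    p$KO2_mito / (s["O2_g"] + p$KO2_mito)^2
  dR["24", "ATP_g"] <- p$Vmax_out_g * o2g * nhg *
    p$Km_ADP_g / (ADPg + p$Km_ADP_g)^2 * dADPg
  dR["24", "NADHmito_g"] <- p$Vmax_out_g * o2g * adg *
    p$Km_NADH_g / (nmg + p$Km_NADH_g)^2

  dR["25", "NADHcyto_n"] <- p$TNADH_n * fpn *
    p$Mcyto_n / (Rmn + p$Mcyto_n)^2 * Ntot / (Ntot - ncn)^2
  dR["25", "NADHmito_n"] <- p$TNADH_n * fmn *
    p$Mmito_n / (Rpn + p$Mmito_n)^2 * (-Ntot / nmn^2)
  dR["26", "NADHcyto_g"] <- p$TNADH_g * fpg *
    p$Mcyto_g / (Rmg + p$Mcyto_g)^2 * Ntot / (Ntot - ncg)^2
  dR["26", "NADHmito_g"] <- p$TNADH_g * fmg *
    p$Mmito_g / (Rpg + p$Mmito_g)^2 * (-Ntot / nmg^2)

  dR["27f", "ATP_n"] <- p$kCKp_n * dADPn * s["PCr_n"]
  dR["27f", "PCr_n"] <- p$kCKp_n * ADPn
  dR["27b", "ATP_n"] <- p$kCKm_n * (Ctot - s["PCr_n"])
  dR["27b", "PCr_n"] <- -p$kCKm_n * s["ATP_n"]
  dR["28f", "ATP_g"] <- p$kCKp_g * dADPg * s["PCr_g"]
  dR["28f", "PCr_g"] <- p$kCKp_g * ADPg
  dR["28b", "ATP_g"] <- p$kCKm_g * (Ctot - s["PCr_g"])
  dR["28b", "PCr_g"] <- -p$kCKm_g * s["ATP_g"]

  dO2cap <- p$KO2 / p$nh_O2 * yc^(-1 / p$nh_O2 - 1) * p$HbOP / s["O2_c"]^2
  dR["29", "O2_c"] <- p$PScapVn * dO2cap
  dR["29", "O2_n"] <- -p$PScapVn
  dR["30", "O2_c"] <- p$PScapVg * dO2cap
  dR["30", "O2_g"] <- -p$PScapVg
  dR["31", "O2_c"] <- -2 * Fv / p$Vcap
  dR["32", "GLC_c"] <- -2 * Fv / p$Vcap
  dR["33", "LAC_c"] <- -2 * Fv / p$Vcap

  dR["34", "ATP_n"] <- dS1 * p$JATPases_n
  dR["35", "ATP_g"] <- dS2 * p$JATPases_g
  dR["36", "ATP_g"] <- dS2 * p$Jpump0_g

  dR["37", "Vv"] <- vo$ddVv_dVv
  dR["38", "O2_c"] <- -2 * Fv
  dR["39", "dHb"] <- vo$Fout / s["Vv"]
  dR["39", "Vv"] <- -vo$ddVv_dVv * s["dHb"] / s["Vv"] -
    vo$Fout * s["dHb"] / s["Vv"]^2

  # closure-scaled copies: grad(S * Rbase) = S * grad(Rbase) + Rbase * S' e_ATP
  scale_n <- function(lab, base) {
    dR[lab, ] <<- S1 * dR[base, ]
    dR[lab, "ATP_n"] <<- dR[lab, "ATP_n"] + R[base] * dS1
  }
  scale_g <- function(lab, base) {
    dR[lab, ] <<- S2 * dR[base, ]
    dR[lab, "ATP_g"] <<- dR[lab, "ATP_g"] + R[base] * dS2
  }
  scale_n("54", "9");  scale_g("55", "10")
  scale_n("56", "11"); scale_g("57", "12")
  scale_n("58", "13"); scale_g("59", "14")
  scale_n("60", "3");  scale_g("61", "4")
  scale_n("62", "22"); scale_g("63", "24")
  scale_n("64f", "27f"); scale_n("64b", "27b")
  scale_g("65f", "28f"); scale_g("65b", "28b")

  list(R = R, dR = dR)
}

#' Compute the rate vector
#'
#' @inheritParams rate_system
#' @return Named numeric vector over [reaction_labels()].
#' @export
compute_rates <- function(state, params, t = 0, protocol = null_protocol()) {
  rate_system(state, params, t, protocol, gradients = FALSE)$R
}
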