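#' Constant stoichiometric matrix
#'
#' The 29 x 67 matrix `S` such that `d(state)/dt = S %*% R(state, t)`.
#' Entries combine the published integer/fractional coefficients with the
#' volume-ratio constants `c1`, `c2`, `r1`-`r5` (see [default_parameters()]);
#' the state-dependent adenylate factors live in the rates (labels 54-65),
#' never here, so the matrix is state independent.
#'
#' @param params Parameter list from [default_parameters()].
#' @return Numeric matrix with dimnames `(state_names(), reaction_labels())`.
#' @export
stoichiometric_matrix <- function(params = default_parameters()) {
  p <- params
  S <- matrix(0, 29, 67, dimnames = list(state_names(), reaction_labels()))
  add <- function(var, ...) {
    co <- c(...)
    S[var, names(co)] <<- S[var, names(co)] + co
  }
  add("Na_n", "1" = 1, "3" = -3, "40" = 1)
  add("Na_g", "2" = 1, "4" = -3, "41" = 1)
  add("GLC_n", "5f" = 1, "5b" = -1, "9" = -1)
  add("GLC_g", "6f" = 1, "6b" = -1, "7f" = 1, "7b" = -1, "10" = -1)
  add("GAP_n", "9" = 2, "11" = -1)
  add("GAP_g", "10" = 2, "12" = -1)
  add("PEP_n", "11" = 1, "13" = -1)
  add("PEP_g", "12" = 1, "14" = -1)
  add("PYR_n", "13" = 1, "15f" = -1, "15b" = 1, "21" = -1)
  add("PYR_g", "14" = 1, "16f" = -1, "16b" = 1, "23" = -1)
  add("LAC_n", "15f" = 1, "15b" = -1, "17f" = -1, "17b" = 1)
  add("LAC_g", "16f" = 1, "16b" = -1, "18f" = -1, "18b" = 1,
      "19f" = -1, "19b" = 1)
  add("NADHcyto_n", "11" = p$c1, "15f" = -p$c1, "15b" = p$c1, "25" = -p$c1)
  add("NADHcyto_g", "12" = p$c1, "16f" = -p$c1, "16b" = p$c1, "26" = -p$c1)
  add("NADHmito_n", "21" = 4 * p$c2, "22" = -p$c2, "25" = p$c2)
  add("NADHmito_g", "23" = 4 * p$c2, "24" = -p$c2, "26" = p$c2)
  add("ATP_n", "54" = -2, "56" = 1, "58" = 1, "34" = -1, "60" = -1,
      "62" = 3.6, "64f" = 1, "64b" = -1)
  add("ATP_g", "55" = -2, "57" = 1, "59" = 1, "35" = -1, "36" = 0.75,
      "61" = -1.75, "63" = 3.6, "65f" = 1, "65b" = -1)
  add("PCr_n", "27f" = -1, "27b" = 1)
  add("PCr_g", "28f" = -1, "28b" = 1)
  add("O2_n", "29" = 1, "22" = -0.6)
  add("O2_g", "30" = 1, "24" = -0.6)
  add("O2_c", "31" = 1, "29" = -p$r1, "30" = -p$r2)
  add("GLC_c", "32" = 1, "7f" = -p$r2, "7b" = p$r2, "8f" = -p$r3, "8b" = p$r3)
  # capillary lactate gains what glia export (r2-scaled) and what the
  # extracellular space exports (r3-scaled)
  add("LAC_c", "33" = 1, "19f" = p$r2, "19b" = -p$r2, "20f" = p$r3,
      "20b" = -p$r3)
  add("Vv", "37" = 1)
  add("dHb", "38" = 1, "39" = -1)
  add("GLC_e", "5f" = -p$r4, "5b" = p$r4, "6f" = -p$r5, "6b" = p$r5,
      "8f" = 1, "8b" = -1)
  add("LAC_e", "17f" = p$r4, "17b" = -p$r4, "18f" = p$r5, "18b" = -p$r5,
      "20f" = -1, "20b" = 1)
  S
}
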