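#' Adenylate pool closures
#'
#' ADP and AMP are slaved to ATP through the adenylate kinase equilibrium
#' `qAK * ADP^2 = ATP * AMP` with the conserved pool
#' `A_tot = ATP + ADP + AMP`. Eliminating AMP gives the closed form
#' `ADP = (ATP/2) * (-qAK + sqrt(qAK^2 + 4 qAK (A_tot/ATP - 1)))`.
#'
#' @param ATP ATP concentration (mM), in `(0, A_tot]`.
#' @param params Parameter list from [default_parameters()].
#' @return ADP concentration (mM).
#' @export
adp_from_atp <- function(ATP, params) {
  A <- params$A_tot; q <- params$qAK
  if (any(ATP <= 0)) stop("ATP must be positive")
  if (any(ATP > A + 1e-12)) stop("ATP exceeds the adenine pool A_tot")
  u <- sqrt(q^2 + 4 * q * (A / ATP - 1))
  (ATP / 2) * (-q + u)
}

#' @rdname adp_from_atp
#' @export
amp_from_atp <- function(ATP, params) {
  params$A_tot - ATP - adp_from_atp(ATP, params)
}

# dADP/dATP of the closed form; used by rate gradients.
dadp_datp <- function(ATP, params) {
  A <- params$A_tot; q <- params$qAK
  u <- sqrt(q^2 + 4 * q * (A / ATP - 1))
  -q / 2 + u / 2 - q * A / (ATP * u)
}

#' Stoichiometric closure factor for the ATP equations
#'
#' Because AMP is slaved to ATP, a reaction that nominally converts one ATP
#' changes the free ATP concentration by the factor
#' `S = (1 - dAMP/dATP)^(-1)`, with
#' `dAMP/dATP = -1 + qAK/2 - u/2 + qAK * A_tot / (ATP * u)` and
#' `u = sqrt(qAK^2 + 4 qAK (A_tot/ATP - 1))`. `S1` (neuronal) and `S2`
#' (astrocytic) are this function evaluated at `ATP_n` and `ATP_g`. Moving
#' the factor into the rate (rather than the stoichiometry) keeps the
#' stoichiometric matrix state-independent.
#'
#' @inheritParams adp_from_atp
#' @return Dimensionless factor `S > 0`.
#' @export
amp_closure_factor <- function(ATP, params) {
  A <- params$A_tot; q <- params$qAK
  if (any(ATP <= 0) || any(ATP >= A)) stop("ATP must lie in (0, A_tot)")
  disc <- q^2 + 4 * q * (A / ATP - 1)
  if (any(disc <= 0)) stop("closure factor undefined: non-real u at this ATP")
  u <- sqrt(disc)
  damp <- -1 + q / 2 - u / 2 + q * A / (ATP * u)
  1 / (1 - damp)
}

# dS/dATP, analytic; S = 1/(1 - m), m = dAMP/dATP, so S' = m' S^2.
damp_closure_factor <- function(ATP, params) {
  A <- params$A_tot; q <- params$qAK
  u <- sqrt(q^2 + 4 * q * (A / ATP - 1))
  du <- -2 * q * A / (ATP^2 * u)
  m <- -1 + q / 2 - u / 2 + q * A / (ATP * u)
  dm <- -du / 2 - q * A * (u + ATP * du) / (ATP^2 * u^2)
  S <- 1 / (1 - m)
  dm * S^2
}
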