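#' State variable names of the metabolic model
#'
#' The 29 model variables in canonical order: intracellular sodium, glycolytic
#' intermediates, lactate, the NADH pools, ATP, phosphocreatine and oxygen in
#' the neuronal (`_n`) and astrocytic (`_g`) compartments, the capillary
#' (`_c`) and extracellular (`_e`) metabolites, the venous volume fraction
#' `Vv` and deoxyhemoglobin `dHb`. All concentrations are in mM; `Vv` is
#' dimensionless. This ordering is the public contract for states, vector
#' fields, Jacobian rows/columns and CSP pointer entries.
#'
#' @return Character vector of length 29.
#' @export
state_names <- function() {
  c("Na_n", "Na_g", "GLC_n", "GLC_g", "GAP_n", "GAP_g", "PEP_n", "PEP_g",
    "PYR_n", "PYR_g", "LAC_n", "LAC_g", "NADHcyto_n", "NADHcyto_g",
    "NADHmito_n", "NADHmito_g", "ATP_n", "ATP_g", "PCr_n", "PCr_g",
    "O2_n", "O2_g", "O2_c", "GLC_c", "LAC_c", "Vv", "dHb",
    "GLC_e", "LAC_e")
}

#' Model parameters
#'
#' Loads the versioned parameter configuration shipped with the package
#' (`inst/extdata/model_parameters.yaml`), applies any overrides, and derives
#' the volume-ratio constants used by the compartment bookkeeping:
#' `c1 = 1/(1 - xi)` and `c2 = 1/xi` convert per-cell fluxes to the cytosolic
#' and mitochondrial sub-volumes, while `r1 = Vn/Vcap`, `r2 = Vg/Vcap`,
#' `r3 = Ve/Vcap`, `r4 = Vn/Ve` and `r5 = Vg/Ve` rescale exchange fluxes
#' between compartments of different size.
#'
#' @param overrides Named list of parameter values replacing the shipped
#'   defaults (applied before derived ratios are computed).
#' @param file Optional path to an alternative YAML configuration.
#' @return Named list of class `neurocsp_params`.
#' @export
default_parameters <- function(overrides = NULL, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "model_parameters.yaml", package = "neurocsp")
  }
  p <- yaml::read_yaml(file)
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  p <- lapply(p, as.numeric)
  # derived volume-ratio constants
  p$c1 <- 1 / (1 - p$xi)
  p$c2 <- 1 / p$xi
  p$r1 <- p$Vn / p$Vcap
  p$r2 <- p$Vg / p$Vcap
  p$r3 <- p$Ve / p$Vcap
  p$r4 <- p$Vn / p$Ve
  p$r5 <- p$Vg / p$Ve
  p$ren <- p$Ve / p$Vn
  p$reg <- p$Ve / p$Vg
  p$rce <- p$Vcap / p$Ve
  p$rcn <- p$Vcap / p$Vn
  p$rcg <- p$Vcap / p$Vg
  validate_parameters(p)
  class(p) <- c("neurocsp_params", "list")
  p
}

validate_parameters <- function(p) {
  must_pos <- setdiff(names(p), c("psi_n", "psi_g", "config_version"))
  vals <- unlist(p[must_pos])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- must_pos[!is.finite(unlist(p[must_pos])) | unlist(p[must_pos]) <= 0]
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  }
  if (p$psi_n >= 0 || p$psi_g >= 0) stop("membrane potentials must be negative (mV)")
  if (p$Ve + p$Vcap + p$Vg + p$Vn > 1 + 1e-12) {
    stop("volume fractions Ve + Vcap + Vg + Vn must not exceed 1")
  }
  invisible(p)
}

#' Tabulated resting state
#'
#' The printed resting-state values of the 29 variables (2-4 significant
#' digits). These are close to, but not exactly on, the model's fixed point;
#' [resting_steady_state()] refines them by Newton iteration.
#'
#' @return Named numeric vector of length 29 (mM; `Vv` dimensionless).
#' @export
resting_state <- function() {
  stats::setNames(
    c(8, 15, 1.2, 1.19, 0.0046, 0.0046, 0.015, 0.015, 0.17, 0.17,
      0.6, 0.6, 0.006, 0.1, 0.12, 0.12, 2.2, 2.2, 4.9, 4.9,
      0.028, 0.028, 7, 4.5, 0.55, 0.02, 0.058, 2.48, 0.6),
    state_names())
}

#' Validate a state vector
#'
#' Checks the physical invariants: all concentrations non-negative,
#' `0 < ATP_x < A_tot`, `0 <= PCr_x <= C_tot`, NADH pools within `N_tot`,
#' and `Vv > 0`.
#'
#' @param state Named numeric vector in [state_names()] order.
#' @param params Parameter list from [default_parameters()].
#' @return `state`, invisibly; errors name the offending variable.
#' @export
validate_state <- function(state, params) {
  nm <- state_names()
  if (length(state) != length(nm)) stop("state must have 29 elements")
  if (is.null(names(state))) names(state) <- nm
  neg <- names(state)[state < 0]
  if (length(neg)) stop("negative concentration: ", paste(neg, collapse = ", "))
  for (v in c("ATP_n", "ATP_g")) {
    if (state[[v]] <= 0 || state[[v]] >= params$A_tot)
      stop(v, " must lie in (0, A_tot)")
  }
  for (v in c("PCr_n", "PCr_g")) {
    if (state[[v]] > params$C_tot) stop(v, " exceeds the creatine pool C_tot")
  }
  for (v in c("NADHcyto_n", "NADHcyto_g", "NADHmito_n", "NADHmito_g")) {
    if (state[[v]] > params$N_tot) stop(v, " exceeds the NAD pool N_tot")
  }
  if (state[["Vv"]] <= 0) stop("Vv must be positive")
  invisible(state)
}
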