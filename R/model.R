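#' Vector field of the metabolic model
#'
#' `d(state)/dt = S %*% R(state, t)` with the constant stoichiometric matrix
#' and the full rate vector.
#'
#' @inheritParams rate_system
#' @param S Optional precomputed [stoichiometric_matrix()] (avoids
#'   reassembly in inner loops).
#' @return Named numeric vector of time derivatives.
#' @export
vector_field <- function(state, params, t = 0, protocol = null_protocol(),
                         S = NULL) {
  if (is.null(S)) S <- stoichiometric_matrix(params)
  R <- rate_system(state, params, t, protocol)$R
  drop(S %*% R)
}

#' Analytic Jacobian of the vector field
#'
#' `J = S %*% dR` where `dR` is the K x N matrix of analytic rate gradients;
#' equal to the sum of the per-reaction Jacobians.
#'
#' @inheritParams vector_field
#' @return 29 x 29 matrix with state-name dimnames.
#' @export
jacobian_full <- function(state, params, t = 0, protocol = null_protocol(),
                          S = NULL) {
  if (is.null(S)) S <- stoichiometric_matrix(params)
  rs <- rate_system(state, params, t, protocol, gradients = TRUE)
  S %*% rs$dR
}

#' Per-reaction Jacobian
#'
#' The rank-one contribution `S_k %o% grad(R_k)` of one unidirectional
#' reaction to the full Jacobian; these are the building blocks of the
#' timescale participation index.
#'
#' @inheritParams vector_field
#' @param label Registry label (see [reaction_labels()]).
#' @return 29 x 29 matrix.
#' @export
jacobian_per_reaction <- function(state, params, label, t = 0,
                                  protocol = null_protocol(), S = NULL) {
  if (is.null(S)) S <- stoichiometric_matrix(params)
  if (!label %in% colnames(S)) stop("unknown reaction label: ", label)
  rs <- rate_system(state, params, t, protocol, gradients = TRUE)
  outer(S[, label], rs$dR[label, ])
}

#' BOLD signal
#'
#' `BOLD = Vv0 * ((k1 + k2)(1 - dHb/dHb0) - (k2 + k3)(1 - Vv/Vv0))` with
#' dimensionless constants k1 = 2.22, k2 = 0.46, k3 = 0.43 and the baseline
#' deoxyhemoglobin and venous volume of the resting state.
#'
#' @param dHb Deoxyhemoglobin (mM), `> 0`.
#' @param Vv Venous volume fraction, `> 0`.
#' @param params Parameter list.
#' @return Dimensionless BOLD signal (0 at baseline).
#' @export
bold_signal <- function(dHb, Vv, params = default_parameters()) {
  if (any(dHb <= 0) || any(Vv <= 0)) stop("dHb and Vv must be positive")
  params$Vv0 * ((params$k1 + params$k2) * (1 - dHb / params$dHb0) -
                (params$k2 + params$k3) * (1 - Vv / params$Vv0))
}

#' Refine the resting state to the model's fixed point
#'
#' The tabulated resting values (2-4 significant digits) are only an
#' approximate fixed point of the printed equations. This damped Newton
#' iteration (analytic Jacobian) refines them to the model's own baseline
#' steady state under the null protocol; the fast glycolytic intermediates
#' move by a few percent, the slow pools stay within the printed rounding.
#'
#' @param params Parameter list.
#' @param start Initial guess (default [resting_state()]).
#' @param tol Convergence tolerance on `max |dy/dt|` (mM/s).
#' @param max_iter Maximum Newton steps.
#' @return Named steady-state vector with attribute `residual`.
#' @export
resting_steady_state <- function(params = default_parameters(),
                                 start = resting_state(),
                                 tol = 1e-12, max_iter = 200) {
  proto <- null_protocol(params = params)
  S <- stoichiometric_matrix(params)
  y <- start
  lower <- rep(1e-9, 29)
  for (it in seq_len(max_iter)) {
    g <- vector_field(y, params, 0, proto, S = S)
    if (max(abs(g)) < tol) break
    J <- jacobian_full(y, params, 0, proto, S = S)
    step <- tryCatch(solve(J, -g), error = function(e) {
      solve(J + diag(1e-10, 29), -g)
    })
    lam <- 1
    repeat {
      y_new <- pmax(y + lam * step, lower)
      g_new <- tryCatch(vector_field(y_new, params, 0, proto, S = S),
                        error = function(e) NULL)
      if (!is.null(g_new) && max(abs(g_new)) < max(abs(g))) break
      lam <- lam / 2
      if (lam < 1e-8) { y_new <- y; g_new <- g; break }
    }
    if (identical(y_new, y)) break
    y <- y_new
  }
  g <- vector_field(y, params, 0, proto, S = S)
  structure(y, residual = max(abs(g)))
}
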