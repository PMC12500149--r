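# Toy multiscale systems with analytically known eigenstructure, used to
# validate the CSP engine independently of the brain model. Each generator
# returns the same interface the engine consumes (stoichiometry, rates,
# rate gradients) together with closed-form reference quantities.

#' Linear two-timescale toy system
#'
#' A 2-D linear system `dy/dt = A y` with eigenvalues `-1/eps` (fast) and
#' `-1` (slow) and right eigenvectors `v_fast = (1, 0)` and
#' `v_slow = (cos(angle), sin(angle))`. Written as two "reactions", one per
#' mode: `S_k = v_k`, `R_k(y) = lambda_k * (w_k . y)` with `w_k` the rows of
#' the inverse eigenvector matrix, so every CSP quantity has a closed form:
#' the decomposition returns exactly `v_k`/`w_k`, the TPI of mode `n` is
#' concentrated (-100%) on reaction `n`, and the fast-mode pointer is the
#' unit vector on the fast coordinate when the eigenvectors are orthogonal.
#'
#' @param eps Timescale-gap parameter in `(0, 1)` (fast timescale = `eps`).
#' @param angle Angle of the slow eigenvector (radians); `pi/2` gives an
#'   orthogonal pair.
#' @return Object of class `neurocsp_toy`: list with `dim`, `S`, `rates(y)`,
#'   `rate_grad(y)`, `field(y)`, `jac(y)`, `solution(y0, t)` (exact),
#'   `eigenvalues`, `V` (right), `W` (left), `eps`.
#' @export
linear_two_scale_system <- function(eps, angle = pi / 2) {
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  lam <- c(-1 / eps, -1)
  V <- cbind(c(1, 0), c(cos(angle), sin(angle)))
  if (abs(det(V)) < 1e-12) stop("degenerate eigenvector angle")
  W <- solve(V)
  A <- V %*% diag(lam) %*% W
  S <- V
  colnames(S) <- c("fast", "slow")
  rates <- function(y) stats::setNames(lam * drop(W %*% y), colnames(S))
  rate_grad <- function(y) {
    out <- lam * W
    rownames(out) <- colnames(S)
    out
  }
  structure(list(
    dim = 2L, S = S, rates = rates, rate_grad = rate_grad,
    field = function(y) drop(A %*% y),
    jac = function(y) A,
    solution = function(y0, t) {
      z0 <- drop(W %*% y0)
      drop(V %*% (z0 * exp(lam * t)))
    },
    eigenvalues = lam, V = V, W = W, eps = eps, angle = angle),
    class = "neurocsp_toy")
}

#' Reversible enzyme toy system (substrate + complex)
#'
#' The classical substrate/enzyme-complex pair with reversible binding and
#' catalysis: `S + E <-> C -> P + E` under enzyme conservation
#' `E = E0 - C`. Variables `y = (S, C)`; three unidirectional reactions:
#' binding (`k1 * S * (E0 - C)`), unbinding (`km1 * C`) and catalysis
#' (`k2 * C`). For `E0 << S0` the binding/unbinding pair is fast and the
#' system collapses onto the quasi-steady-state manifold
#' `C = E0 * S / (Km + S)` with `Km = (km1 + k2) / k1`; the fast-mode
#' pointer concentrates on the complex and the fast-mode API splits
#' approximately +0.5/-0.5 over the binding pair.
#'
#' @param k1,km1,k2 Rate constants (`> 0`).
#' @param E0 Total enzyme; `E0 << S0` for a strong timescale gap.
#' @param S0 Reference initial substrate.
#' @return Object of class `neurocsp_toy` with the engine interface plus
#'   `qssa_manifold(S)` and `Km`.
#' @export
enzyme_qssa_system <- function(k1 = 100, km1 = 100, k2 = 10,
                               E0 = 0.01, S0 = 1) {
  stopifnot(k1 > 0, km1 > 0, k2 > 0, E0 > 0, S0 > 0)
  S <- cbind(bind = c(-1, 1), unbind = c(1, -1), cat = c(0, -1))
  rownames(S) <- c("S", "C")
  rates <- function(y) {
    c(bind = k1 * y[1] * (E0 - y[2]), unbind = km1 * y[2], cat = k2 * y[2])
  }
  rate_grad <- function(y) {
    rbind(bind = c(k1 * (E0 - y[2]), -k1 * y[1]),
          unbind = c(0, km1),
          cat = c(0, k2))
  }
  Km <- (km1 + k2) / k1
  structure(list(
    dim = 2L, S = S, rates = rates, rate_grad = rate_grad,
    field = function(y) drop(S %*% rates(y)),
    jac = function(y) S %*% rate_grad(y),
    qssa_manifold = function(Ssub) E0 * Ssub / (Km + Ssub),
    Km = Km, E0 = E0, S0 = S0, k1 = k1, km1 = km1, k2 = k2),
    class = "neurocsp_toy")
}

#' Integrate a toy system
#'
#' @param sys Toy from [linear_two_scale_system()] or
#'   [enzyme_qssa_system()].
#' @param y0 Initial state.
#' @param times Output times.
#' @param rtol,atol Integrator tolerances.
#' @return Matrix of states (one row per time) with a `times` attribute.
#' @export
simulate_toy <- function(sys, y0, times, rtol = 1e-10, atol = 1e-12) {
  sol <- deSolve::lsoda(y0, times, function(t, y, p) list(sys$field(y)),
                        parms = NULL, rtol = rtol, atol = atol)
  structure(unname(sol[, -1, drop = FALSE]), times = sol[, 1])
}

#' CSP decomposition of a toy system at a state
#'
#' @param sys Toy system.
#' @param y State vector.
#' @return List with `decomp`, `S`, `R`, `dR`, `g`, `J` (same shape as
#'   [csp_decomposition()]).
#' @export
toy_csp <- function(sys, y) {
  R <- sys$rates(y)
  dR <- sys$rate_grad(y)
  J <- sys$S %*% dR
  g <- drop(sys$S %*% R)
  dec <- eigendecompose(J, g)
  rownames(dec$A) <- rownames(sys$S)
  list(decomp = dec, S = sys$S, R = R, dR = dR, g = g, J = J)
}
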