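# CSP engine: leading-order mode decomposition at a state, via the right and
# left eigenvectors of the Jacobian, plus the three diagnostic indices and
# the exhausted-mode criterion.

#' Eigen-decomposition of a Jacobian into CSP modes
#'
#' Modes are sorted fastest first (decreasing `|lambda|`, ties broken by real
#' part then original index). Left vectors are the rows of the inverse of
#' the right-eigenvector matrix, so the bi-orthonormality `b^i . a_j =
#' delta_ij` holds to round-off. Complex conjugate pairs are represented by
#' their real invariant-subspace basis (real and imaginary parts of one
#' member), which keeps every diagnostic real; the two members share the
#' timescale `1/|lambda|`. Signs of each `(a_n, b^n)` pair are flipped
#' jointly so that every amplitude `f^n = b^n . g` is non-negative.
#'
#' @param J N x N Jacobian matrix (finite).
#' @param g N-vector field at the same state.
#' @return Object of class `neurocsp_modes`: list with `values` (complex
#'   eigenvalues, sorted), `tau` (timescales, s), `A` (right basis, columns),
#'   `B` (left basis, rows), `f` (amplitudes, `>= 0`), `pair` (integer index
#'   of the conjugate partner, `NA` for real modes), `n` (dimension).
#' @export
eigendecompose <- function(J, g) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), all(is.finite(J)))
  n <- nrow(J)
  e <- eigen(J)
  ord <- order(-Mod(e$values), Re(e$values), seq_len(n))
  lam <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]

  A <- matrix(0, n, n)
  pair <- rep(NA_integer_, n)
  i <- 1
  while (i <= n) {
    if (abs(Im(lam[i])) > 0 && i < n &&
        abs(lam[i + 1] - Conj(lam[i])) <= 1e-9 * (Mod(lam[i]) + 1e-300)) {
      A[, i] <- Re(V[, i]); A[, i + 1] <- Im(V[, i])
      pair[i] <- i + 1L; pair[i + 1] <- i
      i <- i + 2
    } else {
      if (abs(Im(lam[i])) > 1e-9 * (Mod(lam[i]) + 1e-300)) {
        warning("unpaired complex eigenvalue at mode ", i,
                "; using its real part as basis vector")
      }
      A[, i] <- Re(V[, i])
      i <- i + 1
    }
  }
  # normalize columns (eigen() returns unit vectors, but the real-pair
  # columns need rescaling for conditioning)
  nrm <- sqrt(colSums(A^2))
  if (any(nrm == 0)) stop("degenerate eigenbasis: zero basis vector")
  A <- sweep(A, 2, nrm, "/")
  kappa <- rcond(A)
  if (kappa < 1e-12) {
    warning(sprintf(
      "near-defective Jacobian: eigenbasis condition estimate %.2e", kappa))
  }
  B <- solve(A)
  f <- drop(B %*% g)
  flip <- f < 0
  A[, flip] <- -A[, flip, drop = FALSE]
  B[flip, ] <- -B[flip, , drop = FALSE]
  f <- abs(f)
  structure(list(values = lam, tau = 1 / Mod(lam), A = A, B = B, f = f,
                 pair = pair, n = n, rcond = kappa),
            class = "neurocsp_modes")
}

#' @export
print.neurocsp_modes <- function(x, ...) {
  cat("<neurocsp_modes> ", x$n, " modes, tau = ",
      signif(min(x$tau), 3), "..", signif(max(x$tau), 3), " s\n", sep = "")
  invisible(x)
}

#' Amplitude participation index (API)
#'
#' Signed, normalized per-reaction contribution to the amplitude of mode
#' `r`: `P_k^r = (b^r . S_k) R_k / sum_i |(b^r . S_i) R_i|`, with
#' `sum_k |P_k^r| = 1`. For a mode expressing a partial equilibrium of one
#' reversible pair, the two directions carry approximately +0.5 / -0.5.
#'
#' @param decomp Decomposition from [eigendecompose()].
#' @param S Stoichiometric matrix (N x K).
#' @param R Rate vector (length K).
#' @param mode Mode index (fastest-first ordering).
#' @return Named numeric vector over reaction labels; all `NA` (with a
#'   warning) if every projected rate vanishes.
#' @export
amplitude_participation_index <- function(decomp, S, R, mode) {
  stopifnot(mode >= 1, mode <= decomp$n)
  num <- drop(decomp$B[mode, ] %*% S) * R
  tot <- sum(abs(num))
  if (tot == 0) {
    warning("all projected rates vanish for mode ", mode,
            "; API undefined")
    return(stats::setNames(rep(NA_real_, length(R)), colnames(S)))
  }
  stats::setNames(num / tot, colnames(S))
}

#' Timescale participation index (TPI)
#'
#' Signed, normalized per-reaction contribution to the eigenvalue of mode
#' `n`: `J_k^n = c_k^n / sum_i |c_i^n|` with
#' `c_k^n = b^n . grad(S_k R_k) . a_n = (b^n . S_k)(grad R_k . a_n)` and
#' `sum_k c_k^n = lambda_n` (the real part, for a conjugate pair represented
#' on its real basis). Negative entries are dissipative contributions,
#' positive ones explosive.
#'
#' @inheritParams amplitude_participation_index
#' @param dR K x N matrix of rate gradients (from [rate_system()]).
#' @return Named numeric vector over reaction labels, with attribute
#'   `contributions` holding the unnormalized `c_k^n`.
#' @export
timescale_participation_index <- function(decomp, S, dR, mode) {
  stopifnot(mode >= 1, mode <= decomp$n)
  ck <- drop(decomp$B[mode, ] %*% S) * drop(dR %*% decomp$A[, mode])
  tot <- sum(abs(ck))
  structure(stats::setNames(ck / tot, colnames(S)), contributions = ck)
}

#' CSP pointer
#'
#' Per-species association strength of mode `m`:
#' `D^m = diag(a_m b^m)`, summing to one by bi-orthonormality. Entries near
#' one flag quasi-steady-state species.
#'
#' @inheritParams amplitude_participation_index
#' @return Named numeric vector over [state_names()]-style rownames of the
#'   decomposition (sums to 1).
#' @export
csp_pointer <- function(decomp, mode) {
  stopifnot(mode >= 1, mode <= decomp$n)
  d <- decomp$A[, mode] * decomp$B[mode, ]
  names(d) <- rownames(decomp$A) %||% names(decomp$f)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count exhausted modes
#'
#' The accuracy criterion declares the `M` fastest modes exhausted when the
#' displacement they would produce over the first active timescale is below
#' the accuracy target, componentwise:
#' `|tau_{m+1} * sum_{i<=m} a_i f^i| < e_rel * |y| + e_abs`.
#' `M` is the longest prefix of the fastest-first ordering over which this
#' holds for every `m <= M` (each nesting level must itself be a valid
#' fast/slow split, so a still-active intermediate mode blocks the count
#' even when the inequality happens to hold again at larger `m`). A
#' conjugate pair is never split: a prefix ending between the two members of
#' a pair is shortened by one.
#'
#' The default tolerances were calibrated transparently against the
#' activation scenario with [calibrate_tolerances()]; see the methods
#' vignette for the calibration and its rationale.
#'
#' @param decomp Decomposition from [eigendecompose()] (fastest first).
#' @param state State vector `y` (sets the relative-error scale).
#' @param e_rel,e_abs Relative and absolute tolerances (`e_abs` in mM).
#' @return Integer `M` in `[0, N-1]`.
#' @export
count_exhausted_modes <- function(decomp, state,
                                  e_rel = 0.65, e_abs = 1e-6) {
  stopifnot(e_rel > 0, e_abs > 0)
  n <- decomp$n
  rhs <- e_rel * abs(as.numeric(state)) + e_abs
  Af <- sweep(decomp$A, 2, decomp$f, "*")
  err <- apply(Af, 1, cumsum)           # (n modes) x (n components)
  M <- 0L
  for (m in seq_len(n - 1)) {
    if (any(decomp$tau[m + 1] * abs(err[m, ]) >= rhs)) break
    M <- m
  }
  if (M > 0 && !is.na(decomp$pair[M]) && decomp$pair[M] == M + 1) {
    M <- M - 1L
  }
  as.integer(M)
}

#' Full CSP decomposition of the model at a state
#'
#' Convenience wrapper assembling everything the diagnostics need at one
#' time point: rates, gradients, Jacobian, vector field and the mode
#' decomposition.
#'
#' @inheritParams rate_system
#' @param S Optional precomputed stoichiometric matrix.
#' @return List with `decomp`, `S`, `R`, `dR`, `g`, `J`, `state`, `t`.
#' @export
csp_decomposition <- function(state, params, t = 0,
                              protocol = null_protocol(), S = NULL) {
  if (is.null(S)) S <- stoichiometric_matrix(params)
  rs <- rate_system(state, params, t, protocol, gradients = TRUE)
  J <- S %*% rs$dR
  g <- drop(S %*% rs$R)
  dec <- eigendecompose(J, g)
  rownames(dec$A) <- state_names()
  colnames(dec$B) <- state_names()
  list(decomp = dec, S = S, R = rs$R, dR = rs$dR, g = g, J = J,
       state = state, t = t)
}
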