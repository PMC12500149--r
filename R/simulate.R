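#' Integrate the activation scenario
#'
#' Stiff adaptive integration (`deSolve::lsoda` with the analytic Jacobian)
#' of the 29-variable model under a protocol. Integration proceeds in
#' segments split at the protocol breakpoints (stimulation onset/offset, CBF
#' ramp corners) so the solver never steps across a kink; dense output is
#' sampled on the requested grid.
#'
#' @param protocol Protocol from [activation_protocol()] / [null_protocol()].
#' @param params Parameter list.
#' @param initial_state Initial state; default is the refined resting steady
#'   state ([resting_steady_state()]).
#' @param times Output grid (s); default 1 s spacing up to 1000 s and 10 s
#'   beyond, up to `protocol$t_end`.
#' @param rtol,atol Integrator tolerances (tight, because the eigenanalysis
#'   downstream amplifies trajectory error).
#' @return Object of class `neurocsp_trajectory`: list with `times`, `states`
#'   (matrix, one row per time), `params`, `protocol`.
#' @export
integrate_scenario <- function(protocol, params = default_parameters(),
                               initial_state = NULL, times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  if (is.null(initial_state)) initial_state <- resting_steady_state(params)
  initial_state <- stats::setNames(as.numeric(initial_state), state_names())
  validate_state(initial_state, params)
  if (is.null(times)) times <- analysis_grid(protocol$t_end)
  stopifnot(all(diff(times) > 0), times[1] >= 0)

  S <- stoichiometric_matrix(params)
  rhs <- function(t, y, parms) {
    names(y) <- state_names()
    list(drop(S %*% rate_system(y, params, t, protocol)$R))
  }
  jac <- function(t, y, parms) {
    names(y) <- state_names()
    S %*% rate_system(y, params, t, protocol, gradients = TRUE)$dR
  }

  brk <- with(protocol, c(t_on, t_on + lag_on, t_on + lag_on + ramp,
                          t_off, t_off + lag_off, t_off + lag_off + ramp_off))
  brk <- sort(unique(brk[brk > times[1] & brk < max(times)]))
  edges <- c(times[1], brk, max(times))

  out_t <- numeric(0); out_y <- NULL
  y <- initial_state
  for (i in seq_len(length(edges) - 1)) {
    seg <- sort(unique(c(edges[i], times[times > edges[i] & times <= edges[i + 1]],
                         edges[i + 1])))
    sol <- deSolve::lsoda(y, seg, rhs, parms = NULL, jacfunc = jac,
                          jactype = "fullusr", rtol = rtol, atol = atol,
                          maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0) {
      stop("integrator failure in segment starting at t = ", edges[i],
           "; last accepted time ", max(sol[, 1]))
    }
    keep <- sol[, 1] %in% times & !(sol[, 1] %in% out_t)
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    y <- stats::setNames(sol[nrow(sol), -1], state_names())
  }
  ord <- order(out_t)
  traj <- list(times = out_t[ord],
               states = out_y[ord, , drop = FALSE],
               params = params, protocol = protocol)
  colnames(traj$states) <- state_names()
  class(traj) <- c("neurocsp_trajectory", "list")
  traj
}

#' Default analysis grid
#'
#' 1 s spacing in `[0, 1000]` s, 10 s beyond, up to `t_end`.
#'
#' @param t_end End time (s).
#' @param dt_fine,dt_coarse Spacings (s) below/above the 1000 s switch.
#' @return Numeric vector of times.
#' @export
analysis_grid <- function(t_end, dt_fine = 1, dt_coarse = 10) {
  if (t_end <= 1000) return(seq(0, t_end, by = dt_fine))
  c(seq(0, 1000, by = dt_fine),
    seq(1000 + dt_coarse, t_end, by = dt_coarse))
}

#' Interpolate a trajectory state
#'
#' Linear interpolation between grid states (the grid is dense relative to
#' the slow dynamics that the diagnostics probe).
#'
#' @param traj Trajectory from [integrate_scenario()].
#' @param t Time (s) inside the trajectory span.
#' @return Named state vector.
#' @export
state_at <- function(traj, t) {
  if (t < min(traj$times) || t > max(traj$times)) {
    stop("t outside the trajectory span")
  }
  i <- findInterval(t, traj$times)
  if (traj$times[i] == t || i == length(traj$times)) {
    return(stats::setNames(traj$states[i, ], state_names()))
  }
  w <- (t - traj$times[i]) / (traj$times[i + 1] - traj$times[i])
  stats::setNames((1 - w) * traj$states[i, ] + w * traj$states[i + 1, ],
                  state_names())
}

#' @export
print.neurocsp_trajectory <- function(x, ...) {
  cat("<neurocsp_trajectory> ", nrow(x$states), " states, t = ",
      min(x$times), "..", max(x$times), " s\n", sep = "")
  invisible(x)
}

#' BOLD time series of a trajectory
#'
#' The imaging baseline is the trajectory's own initial state (its resting
#' deoxyhemoglobin and venous volume), so the signal starts at zero by
#' construction, as in an experimental baseline-normalized recording.
#'
#' @param traj Trajectory from [integrate_scenario()].
#' @return data.frame with `time` and `bold`.
#' @export
bold_series <- function(traj) {
  p <- traj$params
  p$dHb0 <- unname(traj$states[1, "dHb"])
  p$Vv0 <- unname(traj$states[1, "Vv"])
  data.frame(time = traj$times,
             bold = bold_signal(traj$states[, "dHb"], traj$states[, "Vv"], p))
}
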