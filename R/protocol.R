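#' Activation scenario protocol
#'
#' Defines the in-vivo activation protocol: a presynaptic stimulation window
#' during which the sodium influx rates take constant values
#' `vstim_n`/`vstim_g`, and a trapezoidal cerebral blood flow (CBF) response
#' that rises linearly over `ramp` seconds, with an onset lag of 2 s and an
#' offset lag of 10 s, from the baseline `F0` to `gain * F0`. The published
#' protocol gives the 30 s rise but not the fall duration; a symmetric 30 s
#' linear fall is adopted (configurable via `ramp_off`).
#'
#' @param t_on,t_off Stimulation window (s); defaults 0 and 900.
#' @param vstim_n,vstim_g Stimulation sodium influx rates (mM/s).
#' @param gain CBF gain during activation (dimensionless, default 1.4).
#' @param lag_on,lag_off CBF lag after stimulation onset/offset (s).
#' @param ramp,ramp_off CBF rise/fall durations (s).
#' @param t_end Simulation end time (s).
#' @param params Parameter list (supplies the baseline `F0`).
#' @return List of class `neurocsp_protocol`.
#' @export
activation_protocol <- function(t_on = 0, t_off = 900,
                                vstim_n = 0.15290, vstim_g = 0.059823,
                                gain = 1.4, lag_on = 2, lag_off = 10,
                                ramp = 30, ramp_off = ramp,
                                t_end = 10000,
                                params = default_parameters()) {
  stopifnot(t_on < t_off, t_off < t_end, lag_on >= 0, lag_off >= 0,
            ramp >= 0, ramp_off >= 0)
  proto <- list(t_on = t_on, t_off = t_off,
                vstim_n = vstim_n, vstim_g = vstim_g,
                F0 = params$F0, gain = gain,
                lag_on = lag_on, lag_off = lag_off,
                ramp = ramp, ramp_off = ramp_off, t_end = t_end)
  class(proto) <- c("neurocsp_protocol", "list")
  proto
}

#' Null protocol (no stimulation, baseline CBF)
#'
#' @param t_end Simulation end time (s).
#' @param params Parameter list.
#' @return Protocol with zero stimulation and unit CBF gain.
#' @export
null_protocol <- function(t_end = 900, params = default_parameters()) {
  proto <- list(t_on = 0, t_off = t_end + 1, vstim_n = 0, vstim_g = 0,
                F0 = params$F0, gain = 1, lag_on = 0, lag_off = 0,
                ramp = 0, ramp_off = 0, t_end = t_end)
  class(proto) <- c("neurocsp_protocol", "list")
  proto
}

#' Cerebral blood flow profile
#'
#' Piecewise-linear trapezoid: baseline `F0` until `t_on + lag_on`, linear
#' rise over `ramp` seconds to `gain * F0`, plateau, then from
#' `t_off + lag_off` a linear return to `F0` over `ramp_off` seconds.
#'
#' @param t Time (s), scalar or vector, `t >= 0`.
#' @param protocol Protocol from [activation_protocol()].
#' @return CBF `F(t)` in 1/s.
#' @export
cbf_profile <- function(t, protocol) {
  p <- protocol
  F0 <- p$F0; F1 <- p$gain * p$F0
  r_on0 <- p$t_on + p$lag_on
  r_on1 <- r_on0 + p$ramp
  r_off0 <- p$t_off + p$lag_off
  r_off1 <- r_off0 + p$ramp_off
  up <- if (p$ramp > 0) F0 + (F1 - F0) * (t - r_on0) / p$ramp else F1
  down <- if (p$ramp_off > 0) F1 + (F0 - F1) * (t - r_off0) / p$ramp_off else F0
  out <- ifelse(t < r_on0, F0,
         ifelse(t < r_on1, up,
         ifelse(t < r_off0, F1,
         ifelse(t < r_off1, down, F0))))
  as.numeric(out)
}

#' Stimulation inputs
#'
#' The presynaptic sodium influx rates: `(vstim_n, vstim_g)` for
#' `t_on <= t < t_off`, zero outside the window.
#'
#' @inheritParams cbf_profile
#' @return Numeric vector `c(R40, R41)` in mM/s (for scalar `t`).
#' @export
stimulation_inputs <- function(t, protocol) {
  if (any(t < 0)) stop("t must be non-negative")
  on <- t >= protocol$t_on & t < protocol$t_off
  if (length(t) == 1L) {
    if (on) c(R40 = protocol$vstim_n, R41 = protocol$vstim_g)
    else c(R40 = 0, R41 = 0)
  } else {
    cbind(R40 = ifelse(on, protocol$vstim_n, 0),
          R41 = ifelse(on, protocol$vstim_g, 0))
  }
}

#' Venous balloon outflow
#'
#' The balloon outflow
#' `Fout = F0 * ((Vv/Vv0)^(1/alpha_v) + tau_v/Vv0 * (Vv/Vv0)^(-1/2) * dVv/dt)`
#' depends implicitly on `dVv/dt = Fin - Fout`. Substituting and solving the
#' resulting linear scalar equation gives the closed form
#' `dVv/dt = (Fin - F0 (Vv/Vv0)^(1/alpha_v)) / (1 + F0 tau_v / Vv0 * (Vv/Vv0)^(-1/2))`
#' and `Fout = Fin - dVv/dt`.
#'
#' @param Vv Venous volume fraction, `> 0`.
#' @param Fin Instantaneous inflow `F(t)` (1/s).
#' @param params Parameter list.
#' @return List with `Fout`, `dVv` and the derivative `ddVv_dVv` used by the
#'   analytic Jacobian.
#' @export
venous_outflow <- function(Vv, Fin, params) {
  if (Vv <= 0) stop("unphysical venous volume Vv <= 0")
  F0 <- params$F0; Vv0 <- params$Vv0
  a <- 1 / params$alpha_v
  v <- Vv / Vv0
  kap <- F0 * params$tau_v / Vv0 * v^(-1 / 2)
  den <- 1 + kap
  num <- Fin - F0 * v^a
  dVv <- num / den
  # d(dVv)/dVv for the Jacobian: quotient rule with
  # d num/dVv = -F0 a v^(a-1)/Vv0, d den/dVv = -kap/(2 Vv)
  dnum <- -F0 * a * v^(a - 1) / Vv0
  dden <- -kap / (2 * Vv)
  ddVv <- (dnum * den - num * dden) / den^2
  list(Fout = Fin - dVv, dVv = dVv, ddVv_dVv = ddVv)
}
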