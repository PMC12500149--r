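# shared fixtures: parameters, random physiological states, and a memoized
# full activation scenario (integration + exhausted-mode scan) reused by the
# scenario-level and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

fix_params <- function() {
  if (is.null(.fixture_cache$params)) {
    .fixture_cache$params <- default_parameters()
  }
  .fixture_cache$params
}

# random state within the physical invariants, jittered around rest
rand_state <- function(seed) {
  set.seed(seed)
  y <- resting_state()
  y <- y * exp(stats::runif(29, -0.15, 0.15))
  y[c("ATP_n", "ATP_g")] <- stats::runif(2, 1.6, 2.2)
  y[c("NADHcyto_n", "NADHcyto_g")] <-
    pmin(y[c("NADHcyto_n", "NADHcyto_g")], 0.19)
  y[c("NADHmito_n", "NADHmito_g")] <-
    pmin(y[c("NADHmito_n", "NADHmito_g")], 0.19)
  y[c("PCr_n", "PCr_g")] <- pmin(y[c("PCr_n", "PCr_g")], 9.5)
  y
}

scenario_fixture <- function() {
  if (!is.null(.fixture_cache$scenario)) return(.fixture_cache$scenario)
  p <- fix_params()
  t0 <- proc.time()[["elapsed"]]
  proto <- activation_protocol(params = p, t_end = 10000)
  traj <- integrate_scenario(proto, p)
  scan <- scan_exhausted_modes(traj)
  periods <- segment_periods(scan)
  elapsed <- proc.time()[["elapsed"]] - t0
  .fixture_cache$scenario <- list(params = p, proto = proto, traj = traj,
                                  scan = scan, periods = periods,
                                  elapsed = elapsed)
  .fixture_cache$scenario
}

# diagnostics at a representative time with the dominant mode M + 1
dominant_diags <- function(t) {
  fx <- scenario_fixture()
  y <- state_at(fx$traj, t)
  cs <- csp_decomposition(y, fx$params, t, fx$proto)
  M <- fx$scan$M[fx$scan$time == t]
  mode <- M + 1L
  list(M = M, mode = mode, cs = cs,
       po = csp_pointer(cs$decomp, mode),
       tpi = timescale_participation_index(cs$decomp, cs$S, cs$dR, mode))
}
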