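test_that("linear toy exact solution satisfies its own ODE", {
  sys <- linear_two_scale_system(0.02, angle = 1.1)
  y0 <- c(0.3, -0.4)
  h <- 1e-6
  for (t in c(0.01, 0.5, 2)) {
    y <- sys$solution(y0, t)
    dy_fd <- (sys$solution(y0, t + h) - sys$solution(y0, t - h)) / (2 * h)
    expect_equal(sys$field(y), dy_fd, tolerance = 1e-6)
  }
  expect_error(linear_two_scale_system(1.5), "eps")
})

test_that("enzyme toy: fast-mode API splits over the binding pair after the transient", {
  sys <- enzyme_qssa_system(k1 = 100, km1 = 100, k2 = 10, E0 = 0.01, S0 = 1)
  # relax onto the quasi-steady-state manifold, then diagnose
  st <- simulate_toy(sys, c(S = sys$S0, C = 0), times = c(0, 0.5))
  y <- st[2, ]
  cs <- toy_csp(sys, y)
  api <- amplitude_participation_index(cs$decomp, cs$S, cs$R, 1)
  expect_equal(unname(abs(api[c("bind", "unbind")])), c(0.5, 0.5),
               tolerance = 0.06)
  # positive and negative parts of a cancelling mode each sum to ~0.5
  expect_equal(sum(api[api > 0]), 0.5, tolerance = 0.06)
  expect_equal(sum(api[api < 0]), -0.5, tolerance = 0.06)
})

test_that("enzyme toy: fast-mode pointer concentrates on the complex as E0 -> 0", {
  ptr <- vapply(c(0.03, 0.003), function(E0) {
    sys <- enzyme_qssa_system(E0 = E0)
    st <- simulate_toy(sys, c(S = sys$S0, C = 0), times = c(0, 0.5))
    cs <- toy_csp(sys, st[2, ])
    unname(csp_pointer(cs$decomp, 1)["C"])
  }, 0)
  expect_gt(ptr[2], ptr[1])
  expect_gt(ptr[2], 0.99)
})

test_that("one-mode reduction tracks the QSSA manifold, tighter as the gap widens", {
  err <- vapply(c(0.03, 0.01, 0.003), function(E0) {
    sys <- enzyme_qssa_system(E0 = E0)
    st <- simulate_toy(sys, c(S = sys$S0, C = 0),
                       times = c(0, seq(0.2, 2, by = 0.2)))
    st <- st[-1, , drop = FALSE]  # after the binding transient
    max(abs(st[, 2] - sys$qssa_manifold(st[, 1])) / E0)
  }, 0)
  # relative distance to the manifold decays with the gap parameter E0/Km
  expect_true(all(diff(err) < 0))
})

test_that("linear toy slow-manifold error decays as the timescale-gap ratio", {
  y0 <- c(1, 1); t0 <- 0.5
  errs <- vapply(c(0.2, 0.1, 0.05), function(eps) {
    sys <- linear_two_scale_system(eps, angle = pi / 4)
    # after the fast transient, the fast-mode displacement f tau measures
    # the distance from the slow manifold (exactly, for a linear system)
    y <- sys$solution(y0, t0)
    cs <- toy_csp(sys, y)
    cs$decomp$f[1] * cs$decomp$tau[1]
  }, 0)
  expect_true(all(diff(errs) < 0))
  # closed form: |z_fast(0)| * exp(-t0/eps) (basis columns are unit norm,
  # and v_fast = (1, 0) already is)
  for (i in seq_along(errs)) {
    eps <- c(0.2, 0.1, 0.05)[i]
    sys <- linear_two_scale_system(eps, angle = pi / 4)
    z0 <- drop(sys$W %*% y0)
    expect_equal(errs[i], abs(z0[1]) * exp(-t0 / eps), tolerance = 1e-6)
  }
})
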