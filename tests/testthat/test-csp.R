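test_that("diagonal Jacobian decomposes into scaled unit vectors", {
  J <- diag(c(-100, -1))
  g <- c(0.3, -0.2)
  d <- eigendecompose(J, g)
  expect_equal(d$tau, c(0.01, 1))
  expect_equal(abs(d$A), diag(2), tolerance = 1e-12)
  expect_equal(abs(d$B), diag(2), tolerance = 1e-12)
  expect_true(all(d$f >= 0))
  expect_equal(sort(d$f), sort(abs(g)))
})

test_that("non-diagonal 2x2 system recovers the closed-form eigenpairs", {
  sys <- linear_two_scale_system(0.05, angle = pi / 3)
  y <- c(0.4, 0.7)
  cs <- toy_csp(sys, y)
  expect_equal(Re(cs$decomp$values), sys$eigenvalues, tolerance = 1e-10)
  # basis columns proportional to the analytic eigenvectors
  for (k in 1:2) {
    a <- cs$decomp$A[, k]
    v <- sys$V[, k] / sqrt(sum(sys$V[, k]^2))
    expect_equal(abs(sum(a * v)), 1, tolerance = 1e-10)
  }
  # amplitudes equal |lambda_k (w_k . y)|
  z <- drop(sys$W %*% y)
  expect_equal(sort(cs$decomp$f),
               sort(abs(sys$eigenvalues * z) *
                    sqrt(colSums(sys$V^2))), tolerance = 1e-9)
})

test_that("amplitudes vanish at an exact steady state and M saturates", {
  J <- matrix(c(-5, 1, 0, -0.1), 2, 2)
  d <- eigendecompose(J, c(0, 0))
  expect_equal(d$f, c(0, 0))
  expect_equal(count_exhausted_modes(d, c(1, 1)), 1L)  # N - 1
})

test_that("bi-orthonormality, normalizations and reconstruction hold on the brain model", {
  p <- fix_params()
  proto <- activation_protocol(params = p)
  S <- stoichiometric_matrix(p)
  for (seed in c(2, 9, 17)) {
    y <- rand_state(seed)
    cs <- csp_decomposition(y, p, t = 40, proto, S = S)
    d <- cs$decomp
    # b^i . a_j = delta_ij
    expect_lt(max(abs(d$B %*% d$A - diag(29))), 1e-8)
    # completeness under the sign convention: sum_n a_n f^n = g with f >= 0
    expect_lt(max(abs(drop(d$A %*% d$f) - cs$g)), 1e-6 * max(abs(cs$g)))
    # index normalizations
    for (m in c(1, 5, 18, 29)) {
      api <- amplitude_participation_index(d, cs$S, cs$R, m)
      expect_equal(sum(abs(api)), 1, tolerance = 1e-8)
      tpi <- timescale_participation_index(d, cs$S, cs$dR, m)
      expect_equal(sum(abs(tpi)), 1, tolerance = 1e-8)
      expect_equal(sum(csp_pointer(d, m)), 1, tolerance = 1e-8)
    }
  }
})

test_that("TPI contributions sum to the eigenvalue", {
  p <- fix_params()
  proto <- activation_protocol(params = p)
  S <- stoichiometric_matrix(p)
  for (seed in c(4, 12)) {
    y <- rand_state(seed)
    cs <- csp_decomposition(y, p, t = 200, proto, S = S)
    real_modes <- which(is.na(cs$decomp$pair))
    for (m in real_modes[c(1, length(real_modes) %/% 2, length(real_modes))]) {
      ck <- attr(timescale_participation_index(cs$decomp, cs$S, cs$dR, m),
                 "contributions")
      expect_equal(sum(ck), Re(cs$decomp$values[m]),
                   tolerance = 1e-8 * abs(cs$decomp$values[m]))
    }
  }
})

test_that("one-reaction system carries unit API; parallel decays split by rate", {
  # single reaction: |API| = 1 by normalization
  S1 <- matrix(1, 1, 1, dimnames = list("y", "r1"))
  d <- eigendecompose(matrix(-3, 1, 1), g = 0.5)
  api <- amplitude_participation_index(d, S1, R = 2, mode = 1)
  expect_equal(abs(unname(api)), 1)
  # two parallel decay channels r_k = -k_k y: TPI = (-k1, -k2)/(k1+k2)
  k1 <- 3; k2 <- 1
  S2 <- matrix(c(1, 1), 1, 2, dimnames = list("y", c("r1", "r2")))
  y <- 0.8
  dR <- matrix(c(-k1, -k2), 2, 1, dimnames = list(c("r1", "r2"), "y"))
  J <- S2 %*% dR
  d <- eigendecompose(J, g = drop(S2 %*% c(-k1 * y, -k2 * y)))
  tpi <- timescale_participation_index(d, S2, dR, 1)
  expect_equal(as.numeric(tpi), c(-k1, -k2) / (k1 + k2), tolerance = 1e-12)
})

test_that("exhausted-mode count steps 0 -> 1 across the fast transient of the linear toy", {
  eps <- 0.01
  # oblique eigenvectors, so the fast coordinate keeps slow content and the
  # relative tolerance has a stable scale to work against
  sys <- linear_two_scale_system(eps, angle = pi / 4)
  y0 <- c(1, 0.3)
  e_rel <- 1e-3
  # oracle from the explicit solution: the criterion compares the fast-mode
  # displacement tau_slow * f_fast = (1/eps) |z_fast(0)| e^{-t/eps} against
  # e_rel * |y_1| with |y_1| ~ the slow content of the fast coordinate
  z0 <- drop(sys$W %*% y0)
  y1_slow <- abs(sys$V[1, 2] * z0[2])
  t_star <- eps * log(abs(z0[1]) / (eps * e_rel * y1_slow))
  for (t in c(0.001, 0.5 * t_star)) {
    y <- sys$solution(y0, t)
    M <- count_exhausted_modes(toy_csp(sys, y)$decomp, y, e_rel, 1e-9)
    expect_equal(M, 0L)
  }
  for (t in c(1.5 * t_star, 1)) {
    y <- sys$solution(y0, t)
    M <- count_exhausted_modes(toy_csp(sys, y)$decomp, y, e_rel, 1e-9)
    expect_equal(M, 1L)
  }
})

test_that("fast-mode pointer is the fast coordinate for orthogonal eigenvectors", {
  sys <- linear_two_scale_system(0.01, angle = pi / 2)
  cs <- toy_csp(sys, c(0.5, 0.5))
  expect_equal(unname(csp_pointer(cs$decomp, 1)), c(1, 0), tolerance = 1e-10)
})
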