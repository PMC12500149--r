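test_that("constant count yields a single period per epoch", {
  scan <- data.frame(time = 0:500, M = 7L)
  per <- segment_periods(scan, epoch_boundary = NULL)
  expect_equal(nrow(per), 1)
  expect_equal(per$M, 7)
  expect_equal(per$dominant_mode, 8)
  expect_equal(c(per$start, per$end), c(0, 500))
})

test_that("step sequence segments at the run boundaries", {
  # run-length oracle: 60 s at 17, 560 s at 26, 280 s at 27 on a 1 s grid
  M <- c(rep(17L, 60), rep(26L, 560), rep(27L, 280))
  scan <- data.frame(time = seq_along(M) - 1, M = M)
  per <- segment_periods(scan, epoch_boundary = NULL)
  expect_equal(per$M, c(17, 26, 27))
  expect_equal(per$start, c(0, 60, 620))
  expect_equal(per$end[1:2], c(60, 620))
})

test_that("sub-dwell flickers are absorbed into the closer neighbour", {
  M <- c(rep(5L, 100), rep(6L, 2), rep(5L, 50), rep(9L, 100))
  scan <- data.frame(time = seq_along(M) - 1, M = M)
  per <- segment_periods(scan, min_dwell = 5, epoch_boundary = NULL)
  expect_equal(per$M, c(5, 9))
  # segmentation is idempotent: re-segmenting the periods' own M series
  M2 <- rep(per$M, times = diff(c(per$start, max(scan$time))))
  per2 <- segment_periods(data.frame(time = seq_along(M2) - 1, M = M2),
                          epoch_boundary = NULL)
  expect_equal(per2$M, per$M)
})

test_that("segmentation is invariant to grid refinement", {
  t1 <- seq(0, 900, by = 1)
  M_of_t <- function(t) ifelse(t < 100, 3L, ifelse(t < 500, 8L, 9L))
  per1 <- segment_periods(data.frame(time = t1, M = M_of_t(t1)),
                          epoch_boundary = NULL)
  t2 <- seq(0, 900, by = 0.25)
  per2 <- segment_periods(data.frame(time = t2, M = M_of_t(t2)),
                          epoch_boundary = NULL)
  expect_equal(per1$M, per2$M)
  expect_equal(per1$start, per2$start, tolerance = 1)
})

test_that("epochs are segmented independently at the boundary", {
  tm <- 0:1200
  M <- ifelse(tm < 900, 10L, 10L)  # constant across the boundary
  per <- segment_periods(data.frame(time = tm, M = M), epoch_boundary = 900)
  expect_equal(nrow(per), 2)
  expect_equal(per$epoch, c("activation", "post-activation"))
  expect_equal(per$start, c(0, 900))
})

test_that("representative times prefer tabulated probes, else the midpoint", {
  M <- c(rep(17L, 60), rep(26L, 560), rep(27L, 281))
  scan <- data.frame(time = seq_along(M) - 1, M = M)
  per <- segment_periods(scan, epoch_boundary = NULL)
  expect_equal(per$t_rep, c(25, 500, 850))
  per2 <- segment_periods(scan, epoch_boundary = NULL,
                          representative_times = numeric())
  expect_equal(per2$t_rep, (per2$start + per2$end) / 2)
})

test_that("a stationary trajectory scans to a constant count", {
  p <- fix_params()
  yss <- resting_steady_state(p)
  proto <- null_protocol(t_end = 50, params = p)
  traj <- integrate_scenario(proto, p, initial_state = yss,
                             times = seq(0, 50, by = 10))
  scan <- scan_exhausted_modes(traj)
  expect_equal(length(unique(scan$M)), 1)
  expect_gte(unique(scan$M), 27)  # essentially all modes exhausted at rest
})
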