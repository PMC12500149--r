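# Period segmentation: turn the pointwise exhausted-mode count M(t) into
# maximal constant-M intervals per epoch, with representative-time
# diagnostics attached.

#' Scan the exhausted-mode count along a trajectory
#'
#' Evaluates the CSP decomposition and the exhausted-mode criterion at every
#' grid point of the trajectory.
#'
#' @param traj Trajectory from [integrate_scenario()].
#' @param e_rel,e_abs Criterion tolerances (see [count_exhausted_modes()]).
#' @param times Optional subset of grid times (default: all).
#' @return data.frame of class `neurocsp_mscan` with columns `time`, `M`
#'   (exhausted-mode count) and `tau_dom` (timescale of mode M+1, s).
#' @export
scan_exhausted_modes <- function(traj, e_rel = 0.65, e_abs = 1e-6,
                                 times = NULL) {
  if (is.null(times)) times <- traj$times
  stopifnot(all(times %in% traj$times))
  S <- stoichiometric_matrix(traj$params)
  idx <- match(times, traj$times)
  M <- integer(length(times)); tau_dom <- numeric(length(times))
  for (i in seq_along(times)) {
    y <- stats::setNames(traj$states[idx[i], ], state_names())
    cs <- csp_decomposition(y, traj$params, times[i], traj$protocol, S = S)
    M[i] <- count_exhausted_modes(cs$decomp, y, e_rel, e_abs)
    tau_dom[i] <- if (M[i] < cs$decomp$n) cs$decomp$tau[M[i] + 1] else NA_real_
  }
  structure(data.frame(time = times, M = M, tau_dom = tau_dom),
            class = c("neurocsp_mscan", "data.frame"),
            e_rel = e_rel, e_abs = e_abs)
}

# run-length encode M over a time grid; returns data.frame(start, end, M)
# where end is the start of the next run (or the last grid time).
.rle_runs <- function(time, M) {
  r <- rle(M)
  starts <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  ends <- cumsum(r$lengths)
  data.frame(start = time[starts],
             end = c(time[starts[-1]], time[ends[length(ends)]]),
             M = r$values)
}

#' Segment an M(t) series into periods
#'
#' Maximal runs of constant exhausted-mode count. Runs shorter than
#' `min_dwell` are debounced: each is absorbed into the neighbouring run
#' with the closer M. The two epochs (activation, post-activation) are
#' segmented independently at `epoch_boundary`.
#'
#' @param scan Output of [scan_exhausted_modes()] (columns `time`, `M`).
#' @param min_dwell Minimum period duration (s, default 5): shorter runs are
#'   merged into a neighbour.
#' @param epoch_boundary Stimulation offset time (s); `NULL` for a single
#'   epoch.
#' @param representative_times Candidate representative times; the first one
#'   falling inside a period is used, otherwise the period midpoint.
#' @return data.frame of class `neurocsp_periods`: `label`, `epoch`,
#'   `start`, `end`, `M`, `dominant_mode` (= M+1), `t_rep`.
#' @export
segment_periods <- function(scan, min_dwell = 5, epoch_boundary = 900,
                            representative_times = c(25, 500, 850, 950,
                                                     1000, 1300, 2000, 6500)) {
  stopifnot(nrow(scan) > 0, !is.unsorted(scan$time))
  epochs <- if (is.null(epoch_boundary)) {
    list(whole = scan)
  } else {
    list(activation = scan[scan$time < epoch_boundary, , drop = FALSE],
         `post-activation` = scan[scan$time >= epoch_boundary, , drop = FALSE])
  }
  out <- NULL
  for (ep in names(epochs)) {
    d <- epochs[[ep]]
    if (nrow(d) == 0) next
    runs <- .rle_runs(d$time, d$M)
    # debounce: iteratively absorb the shortest sub-dwell run
    repeat {
      dur <- runs$end - runs$start
      short <- which(dur < min_dwell)
      if (nrow(runs) <= 1 || !length(short)) break
      i <- short[which.min(dur[short])]
      nb <- c(if (i > 1) i - 1, if (i < nrow(runs)) i + 1)
      j <- nb[which.min(abs(runs$M[nb] - runs$M[i]))]
      runs$M[i] <- runs$M[j]
      # re-encode
      keep <- c(TRUE, diff(runs$M) != 0)
      grp <- cumsum(keep)
      runs <- data.frame(start = tapply(runs$start, grp, min),
                         end = tapply(runs$end, grp, max),
                         M = tapply(runs$M, grp, `[`, 1))
      rownames(runs) <- NULL
    }
    runs$epoch <- ep
    out <- rbind(out, runs)
  }
  out$label <- paste0("P", seq_len(nrow(out)))
  out$dominant_mode <- out$M + 1L
  out$t_rep <- vapply(seq_len(nrow(out)), function(i) {
    cand <- representative_times[representative_times >= out$start[i] &
                                 representative_times < out$end[i]]
    if (length(cand)) cand[1] else (out$start[i] + out$end[i]) / 2
  }, 0)
  out <- out[, c("label", "epoch", "start", "end", "M",
                 "dominant_mode", "t_rep")]
  class(out) <- c("neurocsp_periods", "data.frame")
  out
}

#' Calibration scan for the exhausted-mode tolerances
#'
#' The accuracy tolerances of the exhausted-mode criterion are not intrinsic
#' to the model; this utility reports the grid of resulting M counts at
#' probe times so a choice of `(e_rel, e_abs)` can be made transparently.
#'
#' @param traj Trajectory from [integrate_scenario()].
#' @param probe_times Times (s) at which to count exhausted modes.
#' @param e_rel_grid,e_abs_grid Tolerance grids.
#' @return data.frame with one row per `(e_rel, e_abs)` combination and one
#'   `M_<t>` column per probe time.
#' @export
calibrate_tolerances <- function(traj,
                                 probe_times = c(25, 500, 850, 950, 1000,
                                                 1300, 2000, 6500),
                                 e_rel_grid = c(0.05, 0.1, 0.2, 0.4, 0.55,
                                                0.65, 0.75, 1),
                                 e_abs_grid = c(1e-7, 1e-6, 1e-5)) {
  S <- stoichiometric_matrix(traj$params)
  probe_times <- probe_times[probe_times >= min(traj$times) &
                             probe_times <= max(traj$times)]
  decs <- lapply(probe_times, function(t) {
    y <- state_at(traj, t)
    list(y = y,
         d = csp_decomposition(y, traj$params, t, traj$protocol, S = S)$decomp)
  })
  grid <- expand.grid(e_rel = e_rel_grid, e_abs = e_abs_grid)
  Ms <- t(vapply(seq_len(nrow(grid)), function(i) {
    vapply(decs, function(x) {
      count_exhausted_modes(x$d, x$y, grid$e_rel[i], grid$e_abs[i])
    }, 0L)
  }, integer(length(decs))))
  colnames(Ms) <- paste0("M_", probe_times)
  cbind(grid, Ms)
}
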