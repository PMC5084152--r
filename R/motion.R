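# Motion-pattern analysis: transient-velocity decomposition of trajectories
# and classification into the four motion states (ST, DP, AR, RR) in the 2-D
# (sustained, transient) speed space.

#' Framewise velocities of a trajectory
#'
#' `v_i = (p_i - p_{i-1}) / dt` for `i >= 2` (forward-in-time displacement,
#' so anterograde motion along the anterograde axis has positive projection).
#' Requires uniform sampling; interpolated gap samples are allowed.
#'
#' @param traj A [trajectory()] with at least 2 samples and contiguous
#'   frames.
#' @param dt Frame interval, s.
#' @return Data frame with columns `frame` (the i-th sample) and `vx, vy, vz`
#'   (um/s).
#' @export
framewise_velocity <- function(traj, dt) {
  n <- nrow(traj)
  if (n < 2L) stop("trajectory must have at least 2 samples")
  if (any(diff(traj$frame) != 1L))
    stop("trajectory must be uniformly sampled (interpolate gaps first)")
  pos <- traj_positions(traj)
  v <- diff(pos) / dt
  data.frame(frame = traj$frame[-1L], vx = v[, 1L], vy = v[, 2L],
             vz = v[, 3L])
}

#' Windowed sustained / transient velocity decomposition at one timepoint
#'
#' Over a centred window of `N` samples (`N/2` before the centre, `N/2 - 1`
#' after), each coordinate is fit against time by ordinary least squares; the
#' sustained velocity is the slope vector. The transient speed is the mean
#' magnitude of the deviations of the framewise velocities inside the window
#' from the sustained velocity, normalised by `N`:
#' `(1/N) * sum_j | proj(v_sustain - v_j) |` over the `N - 1` framewise
#' velocities the window contains, where `proj` is the projection onto the
#' anterograde axis (transport runs along the axon, and the 1-D projection
#' keeps the localisation-noise floor of the estimator below the 0.05 um/s
#' state threshold; the full 3-D deviation norm is also returned). It is
#' exactly 0 on a constant-velocity track and quantifies oscillatory
#' motility without net movement.
#'
#' @param traj A [trajectory()] with contiguous frames.
#' @param i Centre index into the trajectory samples (1-based row).
#' @param N Window size, a power of two.
#' @param dt Frame interval, s.
#' @param anterograde_axis Length-2 unit xy vector; the signed sustained
#'   speed is the projection of the sustained velocity onto it.
#' @return List of class `velocity_decomposition`: `frame`,
#'   `sustained_velocity` (3-vector, um/s), `sustained_speed` (magnitude),
#'   `sustained_signed_speed` (projection), `transient_speed` (along-axis),
#'   `transient_speed_3d` (Euclidean deviation norm), `window`, `valid`
#'   (FALSE when the full window is unavailable, all speeds NA).
#' @export
decompose_window <- function(traj, i, N, dt, anterograde_axis = c(1, 0)) {
  k <- log2(N)
  if (abs(k - round(k)) > 1e-12) stop("N must be a power of two")
  n <- nrow(traj)
  lo <- i - N / 2; hi <- i + N / 2 - 1L
  invalid <- list(frame = traj$frame[i], sustained_velocity = rep(NA_real_, 3L),
                  sustained_speed = NA_real_,
                  sustained_signed_speed = NA_real_,
                  transient_speed = NA_real_, transient_speed_3d = NA_real_,
                  window = N, valid = FALSE)
  class(invalid) <- "velocity_decomposition"
  if (lo < 1L || hi > n) return(invalid)
  if (any(diff(traj$frame[lo:hi]) != 1L)) return(invalid)
  pos <- traj_positions(traj)[lo:hi, , drop = FALSE]
  tt <- (traj$frame[lo:hi]) * dt
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slope <- as.numeric(crossprod(tc, sweep(pos, 2L, colMeans(pos))) / denom)
  v <- diff(pos) / dt                     # N - 1 framewise velocities
  dev <- sweep(-v, 2L, -slope)            # slope - v_j, row-wise
  dev_axis <- dev[, 1L] * anterograde_axis[1L] + dev[, 2L] * anterograde_axis[2L]
  transient <- sum(abs(dev_axis)) / N
  transient_3d <- sum(sqrt(rowSums(dev^2))) / N
  signed <- slope[1L] * anterograde_axis[1L] + slope[2L] * anterograde_axis[2L]
  out <- list(frame = traj$frame[i], sustained_velocity = slope,
              sustained_speed = sqrt(sum(slope^2)),
              sustained_signed_speed = signed,
              transient_speed = transient, transient_speed_3d = transient_3d,
              window = N, valid = TRUE)
  class(out) <- "velocity_decomposition"
  out
}

#' Classify one decomposed timepoint into a motion state
#'
#' With threshold `theta` on both speed components:
#' ST if both sustained and transient speed are below `theta` (no net
#' movement, no motility); DP if the sustained speed is below `theta` but the
#' transient speed is not (oscillation without net displacement); otherwise a
#' running state, AR when the signed sustained speed is positive
#' (anterograde) and RR when it is not.
#'
#' @param dec A valid [decompose_window()] result.
#' @param threshold Speed threshold `theta`, um/s (default 0.05).
#' @return One of `"ST"`, `"DP"`, `"AR"`, `"RR"`.
#' @export
classify_point <- function(dec, threshold = 0.05) {
  if (!isTRUE(dec$valid)) stop("cannot classify an invalid decomposition")
  if (threshold <= 0) stop("threshold must be > 0")
  if (dec$sustained_speed < threshold) {
    if (dec$transient_speed < threshold) "ST" else "DP"
  } else {
    if (dec$sustained_signed_speed > 0) "AR" else "RR"
  }
}

#' Decompose and classify every timepoint of a trajectory
#'
#' Slides the `N`-point window over the trajectory; timepoints whose full
#' window is unavailable (edges, or windows crossing a non-contiguous frame
#' run) are flagged invalid and carry no state. Trajectories shorter than
#' `N` yield an all-invalid result with a warning.
#'
#' @param traj A [trajectory()].
#' @param config A [pipeline_config()] (window size, threshold).
#' @param dt Frame interval, s.
#' @param anterograde_axis Length-2 unit xy vector.
#' @param max_interpolated_frac Windows with a larger fraction of
#'   gap-interpolated samples are flagged invalid (default 1 = keep all; the
#'   conservative choice is 0.25).
#' @return Data frame of class `state_series`: one row per timepoint with
#'   columns `track_id, frame, sustained_signed_speed, sustained_speed,
#'   transient_speed, state, valid`.
#' @export
analyze_trajectory <- function(traj, config = pipeline_config(), dt,
                               anterograde_axis = c(1, 0),
                               max_interpolated_frac = 1) {
  N <- config$window_size
  theta <- config$clustering_threshold_speed
  n <- nrow(traj)
  res <- data.frame(track_id = attr(traj, "track_id"), frame = traj$frame,
                    sustained_signed_speed = NA_real_,
                    sustained_speed = NA_real_, transient_speed = NA_real_,
                    state = NA_character_, valid = FALSE)
  if (n < N) {
    warning("trajectory shorter than the analysis window; no valid frames")
    class(res) <- c("state_series", "data.frame")
    return(res)
  }
  for (i in seq_len(n)) {
    dec <- decompose_window(traj, i, N, dt, anterograde_axis)
    if (!dec$valid) next
    lo <- i - N / 2; hi <- i + N / 2 - 1L
    if (mean(traj$interpolated[lo:hi]) > max_interpolated_frac) next
    res$sustained_signed_speed[i] <- dec$sustained_signed_speed
    res$sustained_speed[i] <- dec$sustained_speed
    res$transient_speed[i] <- dec$transient_speed
    res$state[i] <- classify_point(dec, theta)
    res$valid[i] <- TRUE
  }
  class(res) <- c("state_series", "data.frame")
  res
}

#' Per-frame state proportions and running speeds across trajectories
#'
#' At each frame, the fraction of valid trajectories in each state (the four
#' fractions sum to 1 wherever any trajectory is valid) and the mean
#' sustained speed restricted to running (AR/RR) timepoints -- the
#' short-term average running speed.
#'
#' @param series_list List of [analyze_trajectory()] results.
#' @return Data frame with columns `frame, n_valid, ST, DP, AR, RR,
#'   mean_run_speed` (per-frame; `mean_run_speed` is `NA` where no
#'   trajectory is running).
#' @export
state_proportions_over_time <- function(series_list) {
  if (!length(series_list)) stop("no state series supplied")
  all_rows <- data.table::rbindlist(lapply(series_list, as.data.frame))
  valid <- all_rows[all_rows$valid & !is.na(all_rows$state), ]
  if (!nrow(valid)) stop("no valid frames in any series")
  frames <- sort(unique(valid$frame))
  out <- data.frame(frame = frames, n_valid = 0L, ST = 0, DP = 0, AR = 0,
                    RR = 0, mean_run_speed = NA_real_)
  for (r in seq_along(frames)) {
    rows <- valid[valid$frame == frames[r], ]
    nv <- nrow(rows)
    out$n_valid[r] <- nv
    for (s in MOTION_STATES) out[[s]][r] <- sum(rows$state == s) / nv
    run <- rows[rows$state %in% c("AR", "RR"), ]
    if (nrow(run)) out$mean_run_speed[r] <- mean(run$sustained_speed)
  }
  out
}

#' Overall state proportions of one or more state series
#'
#' Pools all valid timepoints and returns the fraction in each state.
#'
#' @param series_list List of [analyze_trajectory()] results (or a single
#'   one).
#' @return Named numeric vector over `ST, DP, AR, RR` summing to 1.
#' @export
state_proportions <- function(series_list) {
  if (inherits(series_list, "state_series")) series_list <- list(series_list)
  states <- unlist(lapply(series_list, function(s) s$state[s$valid]))
  if (!length(states)) stop("no valid frames in any series")
  vapply(MOTION_STATES, function(s) mean(states == s), 0)
}

#' Write a state series table to CSV
#'
#' @param series_list List of [analyze_trajectory()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_series <- function(series_list, path) {
  dt <- data.table::rbindlist(lapply(series_list, as.data.frame))
  data.table::fwrite(dt, path)
  invisible(path)
}
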