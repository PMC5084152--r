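# Frame-to-frame data association and track building.

#' Minimum-cost linear assignment (Hungarian / Jonker-Volgonant style)
#'
#' Solves the rectangular assignment problem by shortest augmenting paths.
#' Forbidden pairs may be encoded as `Inf`; rows left unassigned (or assigned
#' only to forbidden columns) come back as `NA`.
#'
#' @param cost Numeric cost matrix (rows assigned to columns, one-to-one).
#' @return List with `assignment` (for each row, the chosen column or `NA`)
#'   and `cost` (total cost over realised pairs).
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L)
    return(list(assignment = rep(NA_integer_, nr), cost = 0))
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) max(abs(finite)) * (max(nr, nc) + 1) + 1 else 1
  n <- max(nr, nc)
  a <- matrix(big, n, n)
  a[seq_len(nr), seq_len(nc)] <- ifelse(is.finite(cost), cost, big)
  # e-maxx shortest augmenting path; indices offset by 1 (column 0 virtual)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= nr && j <= nc && is.finite(cost[i, j]))
      assignment[i] <- j
  }
  total <- sum(cost[cbind(which(!is.na(assignment)),
                          assignment[!is.na(assignment)])])
  list(assignment = assignment, cost = total)
}

#' Assign detections to predicted tracks
#'
#' Cost is the Mahalanobis position distance under each track's predicted
#' innovation covariance (Euclidean distance over the gate-scale when no
#' covariance is available) plus `feature_weight` times a normalised
#' intensity/volume mismatch. Pairs farther apart than `gate` (Euclidean, um)
#' are forbidden; the assignment is globally optimal one-to-one.
#'
#' @param predictions Data frame with columns `x_um, y_um, z_um` and
#'   optionally `intensity`, `volume_vox`, plus an optional list-column `S`
#'   of 3x3 innovation covariances.
#' @param detections Data frame with columns `x_um, y_um, z_um` and
#'   optionally `total_intensity`/`intensity`, `volume_vox`.
#' @param gate Gating distance, um.
#' @param feature_weight Weight of the feature-mismatch term (default 1).
#' @return List with `matches` (2-column matrix: prediction row, detection
#'   row), `births` (unmatched detection rows), `misses` (unmatched
#'   prediction rows).
#' @export
assign_detections <- function(predictions, detections, gate,
                              feature_weight = 1) {
  stopifnot(gate > 0)
  np <- NROW(predictions); nd <- NROW(detections)
  if (np == 0L || nd == 0L)
    return(list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("track", "detection"))),
                births = seq_len(nd), misses = seq_len(np)))
  det_int <- detections$total_intensity
  if (is.null(det_int)) det_int <- detections$intensity
  cost <- matrix(Inf, np, nd)
  for (i in seq_len(np)) {
    dp <- cbind(detections$x_um - predictions$x_um[i],
                detections$y_um - predictions$y_um[i],
                detections$z_um - predictions$z_um[i])
    eucl <- sqrt(rowSums(dp^2))
    S <- if (!is.null(predictions$S)) predictions$S[[i]] else NULL
    d_pos <- if (!is.null(S)) {
      Sinv <- tryCatch(solve(S), error = function(e) NULL)
      if (is.null(Sinv)) eucl / gate
      else sqrt(pmax(rowSums((dp %*% Sinv) * dp), 0))
    } else eucl / gate
    feat <- 0
    if (feature_weight > 0) {
      if (!is.null(predictions$intensity) && !is.null(det_int)) {
        pi_ <- predictions$intensity[i]
        feat <- feat + abs(det_int - pi_) / pmax(abs(det_int) + abs(pi_), 1e-12)
      }
      if (!is.null(predictions$volume_vox) && !is.null(detections$volume_vox)) {
        pv <- predictions$volume_vox[i]
        feat <- feat + abs(detections$volume_vox - pv) /
          pmax(abs(detections$volume_vox) + abs(pv), 1e-12)
      }
    }
    ci <- d_pos + feature_weight * feat
    ci[eucl > gate] <- Inf
    cost[i, ] <- ci
  }
  sol <- hungarian_assign(cost)
  matched <- which(!is.na(sol$assignment))
  matches <- cbind(track = matched, detection = sol$assignment[matched])
  list(matches = matches,
       births = setdiff(seq_len(nd), matches[, 2L]),
       misses = setdiff(seq_len(np), matches[, 1L]))
}

new_track_record <- function(id, det, frame, meas_sd_pos, pixel_size) {
  list(id = id,
       imm = imm_init(c(det$x_um, det$y_um, det$z_um),
                      intensity = det$total_intensity,
                      meas_sd_pos = meas_sd_pos),
       last_frame = frame, consecutive_hits = 1L, misses = 0L,
       confirmed = FALSE,
       frames = frame,
       pos = matrix(c(det$x_um, det$y_um, det$z_um), 1L, 3L),
       intensity = det$total_intensity, volume = det$volume_vox,
       interpolated = FALSE)
}

finalize_track <- function(rec, dt) {
  trajectory(track_id = rec$id, frame = rec$frames,
             x_um = rec$pos[, 1L], y_um = rec$pos[, 2L], z_um = rec$pos[, 3L],
             t_s = (rec$frames - 1L) * dt,
             intensity = rec$intensity, volume_vox = rec$volume,
             interpolated = rec$interpolated)
}

# append a hit, interpolating any gap since the last stored frame
append_hit <- function(rec, det, frame) {
  gap <- frame - rec$frames[length(rec$frames)]
  if (gap > 1L) {
    miss_frames <- (rec$frames[length(rec$frames)] + 1L):(frame - 1L)
    w <- (miss_frames - rec$frames[length(rec$frames)]) / gap
    last_pos <- rec$pos[nrow(rec$pos), ]
    new_pos <- c(det$x_um, det$y_um, det$z_um)
    interp <- outer(1 - w, last_pos) + outer(w, new_pos)
    rec$frames <- c(rec$frames, miss_frames)
    rec$pos <- rbind(rec$pos, interp)
    rec$intensity <- c(rec$intensity, rep(NA_real_, length(miss_frames)))
    rec$volume <- c(rec$volume, rep(NA_real_, length(miss_frames)))
    rec$interpolated <- c(rec$interpolated, rep(TRUE, length(miss_frames)))
  }
  rec$frames <- c(rec$frames, frame)
  rec$pos <- rbind(rec$pos, c(det$x_um, det$y_um, det$z_um))
  rec$intensity <- c(rec$intensity, det$total_intensity)
  rec$volume <- c(rec$volume, det$volume_vox)
  rec$interpolated <- c(rec$interpolated, FALSE)
  rec
}

#' Build trajectories from per-frame detections
#'
#' Frame-sequential predict / assign / update loop: each active track is
#' advanced one frame by the IMM filter, detections are assigned one-to-one
#' within the gating distance, matched tracks are measurement-updated,
#' unmatched detections open tentative tracks (confirmed after 2 consecutive
#' hits), and unmatched tracks coast (prediction only) until `max_gap`
#' consecutive misses terminates them. Gap frames of recovered tracks are
#' filled by linear interpolation and flagged.
#'
#' @param detections_per_frame List (one element per frame, possibly an empty
#'   data frame) of detection tables from [extract_detections()].
#' @param config A [pipeline_config()].
#' @param metadata An [acquisition_metadata()] (frame interval, pixel size).
#' @return List of [trajectory()] objects ordered by track id.
#' @export
build_tracks <- function(detections_per_frame, config = pipeline_config(),
                         metadata) {
  stopifnot(length(detections_per_frame) >= 1L)
  dt <- metadata$frame_interval
  meas_sd_pos <- 0.5 * metadata$pixel_size_xy
  active <- list(); done <- list(); next_id <- 1L
  for (frame in seq_along(detections_per_frame)) {
    dets <- detections_per_frame[[frame]]
    if (is.null(dets)) dets <- data.frame()
    # 1. predict all active tracks one frame ahead
    preds <- NULL
    if (length(active)) {
      for (k in seq_along(active)) {
        active[[k]]$imm <- imm_predict(active[[k]]$imm, dt)
      }
      preds <- data.frame(
        x_um = vapply(active, function(tr) tr$imm$mean[1L], 0),
        y_um = vapply(active, function(tr) tr$imm$mean[2L], 0),
        z_um = vapply(active, function(tr) tr$imm$mean[3L], 0),
        intensity = vapply(active, function(tr) tr$imm$mean[INT_IDX], 0),
        volume_vox = vapply(active, function(tr) {
          v <- tr$volume[!is.na(tr$volume)]
          if (length(v)) v[length(v)] else NA_real_
        }, 0))
      preds$S <- lapply(active, function(tr) imm_position_innovation_cov(tr$imm))
    }
    # 2. assign
    asg <- assign_detections(
      if (is.null(preds)) data.frame() else preds, dets,
      gate = config$gating_distance, feature_weight = config$feature_weight)
    # 3. matched tracks: update
    if (nrow(asg$matches)) for (r in seq_len(nrow(asg$matches))) {
      k <- asg$matches[r, 1L]; j <- asg$matches[r, 2L]
      det <- dets[j, ]
      active[[k]]$imm <- imm_update(
        active[[k]]$imm, c(det$x_um, det$y_um, det$z_um, det$total_intensity))
      active[[k]] <- append_hit(active[[k]], det, frame)
      active[[k]]$last_frame <- frame
      active[[k]]$misses <- 0L
      active[[k]]$consecutive_hits <- active[[k]]$consecutive_hits + 1L
      if (active[[k]]$consecutive_hits >= 2L) active[[k]]$confirmed <- TRUE
    }
    # 4. missed tracks: coast or terminate
    drop <- logical(length(active))
    for (k in asg$misses) {
      active[[k]]$misses <- active[[k]]$misses + 1L
      active[[k]]$consecutive_hits <- 0L
      if (active[[k]]$misses > config$max_gap || !active[[k]]$confirmed)
        drop[k] <- TRUE
    }
    if (any(drop)) {
      for (k in which(drop)) {
        if (active[[k]]$confirmed ||
            length(active[[k]]$frames) >= 2L)
          done[[length(done) + 1L]] <- active[[k]]
      }
      active <- active[!drop]
    }
    # 5. births
    for (j in asg$births) {
      active[[length(active) + 1L]] <-
        new_track_record(next_id, dets[j, ], frame, meas_sd_pos,
                         metadata$pixel_size_xy)
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  keep <- vapply(done, function(tr) tr$confirmed || length(tr$frames) >= 2L,
                 TRUE)
  # single-frame tracks are kept only if nothing longer exists at all
  if (!any(keep) && length(done)) keep <- rep(TRUE, length(done))
  done <- done[keep]
  ids <- vapply(done, function(tr) tr$id, 0L)
  lapply(done[order(ids)], finalize_track, dt = dt)
}

traj_end_velocity <- function(tr, dt, k = 3L) {
  n <- nrow(tr)
  use <- max(1L, n - k):n
  if (length(use) < 2L) return(c(0, 0, 0))
  pos <- traj_positions(tr)[use, , drop = FALSE]
  tt <- tr$frame[use] * dt
  vapply(1:3, function(c_) stats::cov(tt, pos[, c_]) / stats::var(tt), 0)
}

#' Link fragmented tracks and trim short ones
#'
#' Greedy cost-ordered end-to-start linking: a track ending at frame `e` may
#' be linked to one starting at `s` when `1 <= s - e <= max_link_gap` and the
#' end track's linearly extrapolated position at `s` lies within
#' `max_link_dist` of the start. Lowest cost links first (ties: earliest
#' start frame); no two links share a track end. Linked gaps are filled by
#' linear interpolation and flagged. Tracks shorter than `min_length` frames
#' are then removed.
#'
#' @param tracks List of [trajectory()] objects.
#' @param max_link_gap Maximum temporal gap, frames.
#' @param max_link_dist Maximum extrapolated end-to-start distance, um.
#' @param min_length Minimum surviving track length, frames.
#' @param dt Frame interval, s.
#' @return List of [trajectory()] objects.
#' @export
link_and_trim <- function(tracks, max_link_gap = 3L, max_link_dist = 1.5,
                          min_length = 8L, dt = 1.5) {
  stopifnot(max_link_gap >= 1, max_link_dist > 0, min_length >= 1)
  n <- length(tracks)
  if (n >= 2L) {
    cand <- NULL
    starts <- vapply(tracks, function(tr) tr$frame[1L], 0L)
    ends <- vapply(tracks, function(tr) tr$frame[nrow(tr)], 0L)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      gap <- starts[b] - ends[a]
      if (gap < 1L || gap > max_link_gap) next
      va <- traj_end_velocity(tracks[[a]], dt)
      pa <- traj_positions(tracks[[a]])[nrow(tracks[[a]]), ]
      pred <- pa + va * gap * dt
      pb <- traj_positions(tracks[[b]])[1L, ]
      d <- sqrt(sum((pred - pb)^2))
      if (d <= max_link_dist)
        cand <- rbind(cand, c(a = a, b = b, cost = d, start = starts[b]))
    }
    if (!is.null(cand)) {
      cand <- cand[order(cand[, "cost"], cand[, "start"]), , drop = FALSE]
      # union-find over fragments; each end/start used at most once
      parent <- seq_len(n)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      end_used <- logical(n); start_used <- logical(n)
      links <- list()
      for (r in seq_len(nrow(cand))) {
        a <- cand[r, "a"]; b <- cand[r, "b"]
        if (end_used[a] || start_used[b]) next
        if (find(a) == find(b)) next
        end_used[a] <- TRUE; start_used[b] <- TRUE
        parent[find(b)] <- find(a)
        links[[length(links) + 1L]] <- c(a, b)
      }
      if (length(links)) {
        # assemble chains: successor map
        succ <- rep(NA_integer_, n)
        has_pred <- logical(n)
        for (lk in links) { succ[lk[1L]] <- lk[2L]; has_pred[lk[2L]] <- TRUE }
        merged <- list()
        for (h in which(!has_pred)) {
          chain <- h
          while (!is.na(succ[chain[length(chain)]]))
            chain <- c(chain, succ[chain[length(chain)]])
          if (length(chain) == 1L) { merged[[length(merged) + 1L]] <- tracks[[h]]; next }
          df <- as.data.frame(tracks[[chain[1L]]])
          for (b in chain[-1L]) {
            nxt <- as.data.frame(tracks[[b]])
            gap_frames <- setdiff(seq(df$frame[nrow(df)] + 1L,
                                      nxt$frame[1L] - 1L),
                                  integer(0))
            if (df$frame[nrow(df)] + 1L > nxt$frame[1L] - 1L)
              gap_frames <- integer(0)
            if (length(gap_frames)) {
              w <- (gap_frames - df$frame[nrow(df)]) /
                (nxt$frame[1L] - df$frame[nrow(df)])
              p0 <- unlist(df[nrow(df), c("x_um", "y_um", "z_um")])
              p1 <- unlist(nxt[1L, c("x_um", "y_um", "z_um")])
              fill <- data.frame(
                frame = gap_frames, t_s = (gap_frames - 1L) * dt,
                x_um = (1 - w) * p0[1L] + w * p1[1L],
                y_um = (1 - w) * p0[2L] + w * p1[2L],
                z_um = (1 - w) * p0[3L] + w * p1[3L],
                intensity = NA_real_, volume_vox = NA_real_,
                interpolated = TRUE)
              df <- rbind(df, fill)
            }
            df <- rbind(df, nxt)
          }
          merged[[length(merged) + 1L]] <-
            trajectory(track_id = attr(tracks[[chain[1L]]], "track_id"),
                       frame = df$frame, x_um = df$x_um, y_um = df$y_um,
                       z_um = df$z_um, t_s = df$t_s,
                       intensity = df$intensity, volume_vox = df$volume_vox,
                       interpolated = df$interpolated)
        }
        tracks <- merged
      }
    }
  }
  keep <- vapply(tracks, function(tr)
    (tr$frame[nrow(tr)] - tr$frame[1L] + 1L) >= min_length, TRUE)
  tracks[keep]
}

#' Track a full image sequence
#'
#' Convenience pipeline: enhancement, segmentation and tracking with one
#' call.
#'
#' @param seq An [image_sequence_4d()].
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage timings to stderr.
#' @return List of [trajectory()] objects (linked and trimmed).
#' @export
track_sequence <- function(seq, config = pipeline_config(), verbose = FALSE) {
  log_stage <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3L]
  enh <- enhance_sequence(seq, config)
  log_stage("enhancement: %.1f s", proc.time()[3L] - t0)
  t0 <- proc.time()[3L]
  md <- seq$metadata
  dets <- lapply(seq_len(md$n_frames), function(f) {
    segment_frame(get_volume(enh$denoised, f), enh$pp_maps[[f]], md, config,
                  frame = f)
  })
  log_stage("segmentation: %.1f s", proc.time()[3L] - t0)
  t0 <- proc.time()[3L]
  tracks <- build_tracks(dets, config, md)
  tracks <- link_and_trim(tracks, max_link_gap = config$max_gap,
                          max_link_dist = config$gating_distance,
                          min_length = config$min_track_length,
                          dt = md$frame_interval)
  log_stage("tracking: %.1f s", proc.time()[3L] - t0)
  tracks
}
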