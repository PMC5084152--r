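# Synthetic-data simulator: ground-truth trajectories under a four-state
# motor tug-of-war motion model, rendered into noisy 4-D stacks.

MOTION_STATES <- c("ST", "DP", "AR", "RR")

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Default per-frame state-transition matrix
#'
#' Row-stochastic matrix over (ST, DP, AR, RR) at frame interval `dt`.
#' Dwell times echo axonal mitochondria: stationary phases are long-lived
#' (minutes), dynamic pauses short (`dp_mean_duration`, default 12 s, i.e.
#' below the ~15 s typical upper bound), runs last ~15 s, and a dynamic pause
#' is more likely than a stationary phase to transition into a running state.
#'
#' @param dt Frame interval, s.
#' @param dp_mean_duration Mean dynamic-pause dwell time, s.
#' @return 4x4 row-stochastic matrix with dimnames.
#' @export
default_transition_matrix <- function(dt = 1.5, dp_mean_duration = 12) {
  # exit probabilities per frame = dt / mean dwell
  p_exit_st <- dt / 90                    # ST dwell ~ 90 s
  p_exit_dp <- dt / dp_mean_duration      # DP dwell ~ 12 s (< 15 s)
  p_exit_run <- dt / 15                   # AR/RR dwell ~ 15 s
  m <- rbind(
    ST = c(1 - p_exit_st, 0.70 * p_exit_st, 0.15 * p_exit_st, 0.15 * p_exit_st),
    DP = c(0.20 * p_exit_dp, 1 - p_exit_dp, 0.40 * p_exit_dp, 0.40 * p_exit_dp),
    AR = c(0.10 * p_exit_run, 0.60 * p_exit_run, 1 - p_exit_run, 0.30 * p_exit_run),
    RR = c(0.10 * p_exit_run, 0.60 * p_exit_run, 0.30 * p_exit_run, 1 - p_exit_run)
  )
  colnames(m) <- MOTION_STATES
  m
}

#' Motion-model parameters for the simulator
#'
#' The four states are: stationary (ST, anchored), dynamic pause (DP,
#' zero-net-displacement oscillation from fast direction switching), and
#' anterograde / retrograde running (AR / RR, smooth steady runs at roughly
#' 1 um/s).
#'
#' @param transition_matrix 4x4 row-stochastic per-frame transition matrix
#'   over (ST, DP, AR, RR); default [default_transition_matrix()].
#' @param run_speed_mean,run_speed_sd Run speed distribution, um/s. One speed
#'   is drawn per run segment (default mean 1.0).
#' @param dp_oscillation_amplitude Stationary sd of the DP oscillation about
#'   its anchor, um (default 0.3).
#' @param dp_mean_duration Mean DP dwell, s (default 12; used when building
#'   the default transition matrix).
#' @param axis_jitter_sd Off-axis positional jitter sd, um (default 0.02).
#' @param dp_ar1_coef AR(1) coefficient of the DP oscillation; negative
#'   values give the alternating (tug-of-war-like) signature (default -0.5).
#' @return An object of class `motion_model_params`.
#' @export
motion_model_params <- function(transition_matrix = NULL,
                                run_speed_mean = 1.0, run_speed_sd = 0.1,
                                dp_oscillation_amplitude = 0.3,
                                dp_mean_duration = 12,
                                axis_jitter_sd = 0.02,
                                dp_ar1_coef = -0.5) {
  if (is.null(transition_matrix))
    transition_matrix <- default_transition_matrix(dp_mean_duration = dp_mean_duration)
  transition_matrix <- as.matrix(transition_matrix)
  if (!identical(dim(transition_matrix), c(4L, 4L)))
    stop("transition_matrix must be 4x4 over (ST, DP, AR, RR)")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop("transition_matrix rows must be non-negative and sum to 1")
  if (run_speed_mean <= 0) stop("run_speed_mean must be > 0")
  if (dp_mean_duration <= 0) stop("dp_mean_duration must be > 0")
  if (abs(dp_ar1_coef) >= 1) stop("dp_ar1_coef must lie in (-1, 1)")
  dimnames(transition_matrix) <- list(MOTION_STATES, MOTION_STATES)
  structure(list(
    transition_matrix = transition_matrix,
    run_speed_mean = run_speed_mean, run_speed_sd = run_speed_sd,
    dp_oscillation_amplitude = dp_oscillation_amplitude,
    dp_mean_duration = dp_mean_duration,
    axis_jitter_sd = axis_jitter_sd, dp_ar1_coef = dp_ar1_coef
  ), class = "motion_model_params")
}

#' Imaging / rendering parameters for the simulator
#'
#' Forward model: each mitochondrion is an anisotropic 3-D Gaussian blob of
#' peak amplitude decaying exponentially with time (photobleaching), summed
#' onto a constant background, with Poisson shot noise (or additive Gaussian
#' noise for analytic tests).
#'
#' @param psf_sigma_xy,psf_sigma_z Gaussian blob sigmas, um (defaults 0.3 and
#'   0.6: a ~1.4 um object sampled at 0.2 um/px, wider axially).
#' @param background_level,peak_amplitude Intensity offsets (defaults 10 and
#'   100 photons).
#' @param noise_model `list(type = "poisson")` (default) or
#'   `list(type = "gaussian", sd = ...)` or `list(type = "none")`.
#' @param bleach_rate Photobleaching rate, 1/s (default 1e-3: ~26% intensity
#'   loss over a 5-min acquisition).
#' @param groove_spacing Spacing of the parallel axon lines the particles sit
#'   on, um (default 10; a scaled-down microgroove geometry suitable for
#'   small synthetic fields).
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(psf_sigma_xy = 0.3, psf_sigma_z = 0.6,
                           background_level = 10, peak_amplitude = 100,
                           noise_model = list(type = "poisson"),
                           bleach_rate = 1e-3, groove_spacing = 10) {
  if (psf_sigma_xy <= 0 || psf_sigma_z <= 0) stop("PSF sigmas must be > 0")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (!is.list(noise_model) || is.null(noise_model$type) ||
      !noise_model$type %in% c("poisson", "gaussian", "none"))
    stop("noise_model$type must be 'poisson', 'gaussian' or 'none'")
  if (noise_model$type == "gaussian" && is.null(noise_model$sd))
    stop("gaussian noise_model needs an 'sd' element")
  structure(list(
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    background_level = background_level, peak_amplitude = peak_amplitude,
    noise_model = noise_model, bleach_rate = bleach_rate,
    groove_spacing = groove_spacing
  ), class = "imaging_params")
}

#' Simulate a motion-state sequence
#'
#' Realises the first-order Markov chain over (ST, DP, AR, RR) defined by the
#' per-frame transition matrix.
#'
#' @param params A [motion_model_params()].
#' @param n_frames Number of frames.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @param init_state Initial state label; default drawn from the chain's
#'   stationary distribution.
#' @return Character vector of length `n_frames` with values in
#'   `c("ST", "DP", "AR", "RR")`.
#' @export
simulate_state_sequence <- function(params, n_frames, seed = NULL,
                                    init_state = NULL) {
  stopifnot(inherits(params, "motion_model_params"), n_frames >= 1)
  P <- params$transition_matrix
  with_seed(seed, {
    if (is.null(init_state)) {
      init_state <- sample(MOTION_STATES, 1L, prob = stationary_distribution(P))
    }
    s <- match(init_state, MOTION_STATES)
    if (is.na(s)) stop("init_state must be one of ST, DP, AR, RR")
    out <- integer(n_frames)
    out[1L] <- s
    if (n_frames > 1L) for (i in 2:n_frames) {
      out[i] <- sample.int(4L, 1L, prob = P[out[i - 1L], ])
    }
    MOTION_STATES[out]
  })
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `P` with eigenvalue 1, normalised to sum to 1.
#'
#' @param P Row-stochastic square matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, k]))
  stats::setNames(v / sum(v), rownames(P))
}

#' Simulate one trajectory from a state sequence
#'
#' Positions evolve along the anterograde axis: ST holds an anchor, DP is a
#' zero-mean AR(1) oscillation about its anchor, AR/RR step by
#' `+/- run_speed * dt` per frame (one speed drawn per run segment). Off-axis
#' jitter and optional isotropic measurement noise are added on top.
#'
#' @param states Character state labels per frame.
#' @param params A [motion_model_params()].
#' @param dt Frame interval, s.
#' @param seed Optional RNG seed.
#' @param origin Length-3 numeric starting position `(x, y, z)`, um.
#' @param axis Length-2 unit xy vector of the anterograde direction.
#' @param position_noise_sd Isotropic Gaussian measurement noise added to the
#'   reported (not true) positions, um (default 0).
#' @param track_id Track id stored on the trajectory.
#' @return List with `trajectory` (observed positions, a [trajectory()]) and
#'   `truth` (list: `states`, `positions` true n x 3 matrix, `params`).
#' @export
simulate_trajectory <- function(states, params, dt, seed = NULL,
                                origin = c(0, 0, 0), axis = c(1, 0),
                                position_noise_sd = 0, track_id = 1L) {
  stopifnot(inherits(params, "motion_model_params"), dt > 0,
            all(states %in% MOTION_STATES))
  n <- length(states)
  axis <- axis / sqrt(sum(axis^2))
  with_seed(seed, {
    # one speed per contiguous run segment
    rl <- rle(states)
    seg_speed <- numeric(length(rl$lengths))
    for (k in seq_along(rl$lengths)) {
      if (rl$values[k] %in% c("AR", "RR"))
        seg_speed[k] <- max(0.05, stats::rnorm(1, params$run_speed_mean,
                                               params$run_speed_sd))
    }
    seg_of <- rep(seq_along(rl$lengths), rl$lengths)

    rho <- params$dp_ar1_coef
    osc_innov_sd <- params$dp_oscillation_amplitude * sqrt(1 - rho^2)
    s <- numeric(n)          # along-axis coordinate, um
    anchor <- 0; osc <- 0
    prev_state <- ""
    for (i in seq_len(n)) {
      st <- states[i]
      if (i == 1L) {
        s[i] <- 0
        anchor <- 0
      } else {
        switch(st,
          ST = {
            if (prev_state != "ST") anchor <- s[i - 1L]
            s[i] <- anchor
          },
          DP = {
            if (prev_state != "DP") { anchor <- s[i - 1L]; osc <- 0 }
            osc <- rho * osc + stats::rnorm(1, 0, osc_innov_sd)
            s[i] <- anchor + osc
          },
          AR = s[i] <- s[i - 1L] + seg_speed[seg_of[i]] * dt,
          RR = s[i] <- s[i - 1L] - seg_speed[seg_of[i]] * dt
        )
      }
      prev_state <- st
    }
    perp <- c(-axis[2L], axis[1L])
    j1 <- if (params$axis_jitter_sd > 0) stats::rnorm(n, 0, params$axis_jitter_sd) else numeric(n)
    j2 <- if (params$axis_jitter_sd > 0) stats::rnorm(n, 0, params$axis_jitter_sd) else numeric(n)
    true_pos <- cbind(
      x_um = origin[1L] + s * axis[1L] + j1 * perp[1L],
      y_um = origin[2L] + s * axis[2L] + j1 * perp[2L],
      z_um = origin[3L] + j2
    )
    obs <- true_pos
    if (position_noise_sd > 0)
      obs <- obs + matrix(stats::rnorm(3L * n, 0, position_noise_sd), ncol = 3L)
    traj <- trajectory(track_id = track_id, frame = seq_len(n),
                       x_um = obs[, 1L], y_um = obs[, 2L], z_um = obs[, 3L],
                       dt = dt)
    list(trajectory = traj,
         truth = list(states = states, positions = true_pos, params = params))
  })
}

#' Render one 3-D frame of Gaussian blobs
#'
#' Deterministic forward model plus optional noise: for each particle a
#' separable anisotropic Gaussian of amplitude
#' `peak_amplitude * exp(-bleach_rate * (t - 1) * dt)` is added to a constant
#' background; shot noise is applied last. Positions outside the field are
#' clipped to it.
#'
#' @param positions n x 3 matrix of particle positions `(x, y, z)`, um.
#' @param params An [imaging_params()].
#' @param metadata An [acquisition_metadata()] (grid and calibration).
#' @param t 1-based frame index (drives bleaching).
#' @param seed Optional RNG seed for the noise.
#' @return 3-D array `(z, y, x)`.
#' @export
render_frame <- function(positions, params, metadata, t = 1L, seed = NULL) {
  stopifnot(inherits(params, "imaging_params"),
            inherits(metadata, "acquisition_metadata"))
  nz <- metadata$n_z; ny <- metadata$height; nx <- metadata$width
  vol <- array(params$background_level, dim = c(nz, ny, nx))
  if (!is.null(positions) && NROW(positions) > 0) {
    positions <- matrix(as.numeric(positions), ncol = 3L)
    amp <- params$peak_amplitude *
      exp(-params$bleach_rate * (t - 1L) * metadata$frame_interval)
    px <- metadata$pixel_size_xy; zs <- metadata$z_step
    # clip to physical field
    positions[, 1L] <- pmin(pmax(positions[, 1L], 0), (nx - 1L) * px)
    positions[, 2L] <- pmin(pmax(positions[, 2L], 0), (ny - 1L) * px)
    positions[, 3L] <- pmin(pmax(positions[, 3L], 0), (nz - 1L) * zs)
    sx <- params$psf_sigma_xy; sz <- params$psf_sigma_z
    rx <- ceiling(4 * sx / px); rz <- ceiling(4 * sz / zs)
    for (p in seq_len(nrow(positions))) {
      cx <- positions[p, 1L] / px; cy <- positions[p, 2L] / px
      cz <- positions[p, 3L] / zs
      ix <- max(0L, floor(cx - rx)):min(nx - 1L, ceiling(cx + rx))
      iy <- max(0L, floor(cy - rx)):min(ny - 1L, ceiling(cy + rx))
      iz <- max(0L, floor(cz - rz)):min(nz - 1L, ceiling(cz + rz))
      gx <- exp(-((ix - cx) * px)^2 / (2 * sx^2))
      gy <- exp(-((iy - cy) * px)^2 / (2 * sx^2))
      gz <- exp(-((iz - cz) * zs)^2 / (2 * sz^2))
      blob <- amp * (gz %o% gy %o% gx)
      vol[iz + 1L, iy + 1L, ix + 1L] <- vol[iz + 1L, iy + 1L, ix + 1L] + blob
    }
  }
  nm <- params$noise_model
  if (nm$type != "none") {
    vol <- with_seed(seed, {
      if (nm$type == "poisson")
        array(stats::rpois(length(vol), lambda = vol), dim = dim(vol))
      else
        pmax(vol + array(stats::rnorm(length(vol), 0, nm$sd), dim = dim(vol)), 0)
    })
  }
  vol
}

#' Generate a paired synthetic stack and ground truth
#'
#' Particles are seeded on parallel groove lines (constant y, spaced by
#' `groove_spacing`), simulated under the four-state motion model, optionally
#' kept apart by a minimum along-groove spacing (a mover whose step would
#' bring it within `min_spacing_um` of a neighbour stalls at the limit, as a
#' motor does at an obstruction; particle order within a groove never
#' changes), and rendered frame by frame.
#'
#' @param n_particles,n_frames Counts.
#' @param motion A [motion_model_params()].
#' @param imaging An [imaging_params()].
#' @param metadata An [acquisition_metadata()] with grid counts set.
#' @param seed RNG seed (the dataset is fully reproducible given it).
#' @param min_spacing_um Minimum centre-to-centre spacing along a groove, um
#'   (default 2). `NA` disables spacing enforcement.
#' @return List with `sequence` (an [image_sequence_4d()]) and `truth` (list:
#'   `states` particles x frames character matrix, `positions`
#'   particles x frames x 3 array (um), `motion`, `imaging`, `seed`).
#' @export
generate_dataset <- function(n_particles = 50L, n_frames = 100L,
                             motion = motion_model_params(),
                             imaging = imaging_params(),
                             metadata = acquisition_metadata(
                               pixel_size_xy = 0.2, z_step = 1.0,
                               frame_interval = 1.5, n_frames = n_frames,
                               n_z = 5L, height = 256L, width = 256L),
                             seed = NULL, min_spacing_um = 2) {
  metadata$n_frames <- as.integer(n_frames)
  width_um <- (metadata$width - 1L) * metadata$pixel_size_xy
  height_um <- (metadata$height - 1L) * metadata$pixel_size_xy
  grooves_y <- seq(imaging$groove_spacing / 2, height_um,
                   by = imaging$groove_spacing)
  if (length(grooves_y) == 0L) stop("field too small for one groove line")
  spacing <- if (is.na(min_spacing_um)) 0 else min_spacing_um
  if (n_particles > 0 && spacing > 0) {
    capacity <- length(grooves_y) * floor(width_um / spacing)
    if (n_particles > capacity)
      stop(sprintf("field too small: %d particles exceed capacity %d at %.2g um spacing",
                   n_particles, capacity, spacing))
  }
  dt <- metadata$frame_interval
  truth_states <- matrix(character(0), nrow = 0, ncol = n_frames)
  truth_pos <- array(numeric(0), dim = c(0L, n_frames, 3L))
  stack <- array(0, dim = c(n_frames, metadata$n_z, metadata$height,
                            metadata$width))
  with_seed(seed, {
    if (n_particles > 0L) {
      groove_of <- rep(seq_along(grooves_y), length.out = n_particles)
      truth_states <- matrix(NA_character_, n_particles, n_frames)
      truth_pos <- array(NA_real_, dim = c(n_particles, n_frames, 3L))
      mid_z <- (metadata$n_z - 1L) / 2 * metadata$z_step
      for (g in unique(groove_of)) {
        idx <- which(groove_of == g)
        k <- length(idx)
        # evenly spread starting x, jittered but keeping order and spacing
        base_x <- (seq_len(k) - 0.5) / k * width_um
        jit <- stats::runif(k, -0.2, 0.2) * width_um / k
        x0 <- sort(pmin(pmax(base_x + jit, 0), width_um))
        pos_g <- matrix(NA_real_, k, n_frames)   # along-axis coordinates
        for (j in seq_len(k)) {
          p <- idx[j]
          st <- simulate_state_sequence(motion, n_frames)
          sim <- simulate_trajectory(st, motion, dt,
                                     origin = c(x0[j], grooves_y[g], mid_z))
          truth_states[p, ] <- st
          truth_pos[p, , ] <- sim$truth$positions
          pos_g[j, ] <- sim$truth$positions[, 1L]
        }
        if (spacing > 0 && k > 1L) {
          # collision handling: apply each particle's own increments to its
          # actual position, stalling at min spacing from its neighbours
          steps <- t(apply(pos_g, 1L, function(x) c(0, diff(x))))
          act <- pos_g
          if (n_frames > 1L) for (tt in 2:n_frames) {
            for (j in seq_len(k)) {
              desired <- act[j, tt - 1L] + steps[j, tt]
              # field edges act as walls, neighbours as moving obstructions
              lo <- if (j > 1L) act[j - 1L, tt] + spacing else 0
              hi <- if (j < k) act[j + 1L, tt - 1L] - spacing else width_um
              if (lo > hi) desired <- act[j, tt - 1L]
              act[j, tt] <- min(max(desired, lo), hi)
            }
          }
          for (j in seq_len(k)) truth_pos[idx[j], , 1L] <- act[j, ]
        } else {
          truth_pos[idx, , 1L] <- pmin(pmax(truth_pos[idx, , 1L], 0), width_um)
        }
      }
    }
    for (tt in seq_len(n_frames)) {
      pos_t <- if (n_particles > 0L)
        matrix(truth_pos[, tt, ], ncol = 3L) else NULL
      stack[tt, , , ] <- render_frame(pos_t, imaging, metadata, t = tt)
    }
    list(sequence = image_sequence_4d(stack, metadata),
         truth = list(states = truth_states, positions = truth_pos,
                      motion = motion, imaging = imaging, seed = seed))
  })
}

#' Ground-truth trajectories from a generated dataset
#'
#' @param truth The `truth` element of [generate_dataset()].
#' @param dt Frame interval, s.
#' @return List of [trajectory()] objects (one per simulated particle).
#' @export
truth_trajectories <- function(truth, dt) {
  n <- nrow(truth$positions)
  lapply(seq_len(n), function(p) {
    trajectory(track_id = p, frame = seq_len(dim(truth$positions)[2L]),
               x_um = truth$positions[p, , 1L],
               y_um = truth$positions[p, , 2L],
               z_um = truth$positions[p, , 3L], dt = dt)
  })
}
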