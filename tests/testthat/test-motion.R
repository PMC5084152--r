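test_that("framewise velocities are forward differences over dt", {
  tr <- trajectory(1L, frame = 1:3, x_um = c(0, 1.5, 3.0), dt = 1.5)
  v <- framewise_velocity(tr, 1.5)
  expect_equal(v$vx, c(1, 1))
  expect_equal(v$vy, c(0, 0))

  flat <- trajectory(1L, frame = 1:5, x_um = rep(2, 5), dt = 1.5)
  expect_true(all(framewise_velocity(flat, 1.5)$vx == 0))

  # time reversal negates every velocity
  set.seed(3)
  x <- cumsum(rnorm(10))
  fwd <- trajectory(1L, frame = 1:10, x_um = x, dt = 1.5)
  rev_ <- trajectory(1L, frame = 1:10, x_um = rev(x), dt = 1.5)
  expect_equal(framewise_velocity(rev_, 1.5)$vx,
               -rev(framewise_velocity(fwd, 1.5)$vx))

  expect_error(framewise_velocity(trajectory(1L, frame = 1L, x_um = 0), 1.5),
               "at least 2")
})

test_that("decomposition is exact on lines and matches the square-wave closed form", {
  dt <- 1.5
  # exact line: sustained = slope, transient = 0
  for (speed in c(0.1, 0.9, 1.5)) {
    tr <- line_traj(speed, n = 40L, dt = dt)
    for (N in c(8L, 16L, 32L)) {
      dec <- decompose_window(tr, 20L, N, dt)
      expect_true(dec$valid)
      expect_equal(dec$sustained_signed_speed, speed, tolerance = 1e-9)
      expect_equal(dec$transient_speed, 0, tolerance = 1e-9)
    }
  }

  # alternating square wave, N = 16: slope = d / (85 dt) exactly
  d <- 0.3
  tr <- square_wave_traj(d = d, n = 32L, dt = dt)
  dec <- decompose_window(tr, 16L, 16L, dt)
  expect_equal(abs(dec$sustained_signed_speed), d / (85 * dt),
               tolerance = 1e-12)
  # independent least-squares oracle for the same window
  lo <- 16L - 8L; hi <- 16L + 7L
  fit <- stats::lm(tr$x_um[lo:hi] ~ I(tr$frame[lo:hi] * dt))
  expect_equal(dec$sustained_signed_speed, unname(stats::coef(fit)[2L]),
               tolerance = 1e-12)
  # independent transient oracle: mean norm of velocity deviations over N
  v <- diff(tr$x_um[lo:hi]) / dt
  expect_equal(dec$transient_speed,
               sum(abs(dec$sustained_velocity[1L] - v)) / 16L,
               tolerance = 1e-12)
  expect_gt(dec$transient_speed, 0.15)   # ~ d/dt = 0.2 um/s framewise speed
  expect_lt(dec$sustained_speed, 0.05)
  expect_identical(classify_point(dec, 0.05), "DP")

  # translation invariance
  tr2 <- trajectory(1L, frame = tr$frame, x_um = tr$x_um + 100,
                    y_um = tr$y_um - 50, dt = dt)
  dec2 <- decompose_window(tr2, 16L, 16L, dt)
  expect_equal(dec2$sustained_signed_speed, dec$sustained_signed_speed,
               tolerance = 1e-12)
  expect_equal(dec2$transient_speed, dec$transient_speed, tolerance = 1e-12)

  # incomplete window flagged invalid; N validated
  expect_false(decompose_window(tr, 3L, 16L, dt)$valid)
  expect_error(decompose_window(tr, 16L, 12L, dt), "power of two")
})

test_that("classification follows the two-threshold rule", {
  mk <- function(sus, trans, signed = sus) {
    structure(list(frame = 1L, sustained_velocity = c(signed, 0, 0),
                   sustained_speed = sus, sustained_signed_speed = signed,
                   transient_speed = trans, window = 16L, valid = TRUE),
              class = "velocity_decomposition")
  }
  expect_identical(classify_point(mk(0.02, 0.01), 0.05), "ST")
  expect_identical(classify_point(mk(0.02, 0.30), 0.05), "DP")
  expect_identical(classify_point(mk(0.8, 0.1, signed = 0.8), 0.05), "AR")
  expect_identical(classify_point(mk(0.8, 0.1, signed = -0.8), 0.05), "RR")
  # purely off-axis motion above threshold: assigned RR by the stated rule
  expect_identical(classify_point(mk(0.8, 0.1, signed = 0), 0.05), "RR")
  expect_error(classify_point(mk(0.1, 0.1), -1), "threshold")
  bad <- mk(0.1, 0.1); bad$valid <- FALSE
  expect_error(classify_point(bad, 0.05), "invalid")
})

test_that("whole-trajectory analysis labels constructed tracks correctly", {
  dt <- 1.5
  cfg <- pipeline_config()
  # all-AR at 1 um/s: every valid frame AR with signed speed 1.0
  ar <- analyze_trajectory(line_traj(1.0, n = 48L, dt = dt), cfg, dt = dt)
  expect_true(all(ar$state[ar$valid] == "AR"))
  expect_equal(ar$sustained_signed_speed[ar$valid],
               rep(1, sum(ar$valid)), tolerance = 1e-9)
  # edges flagged invalid: window needs N/2 points before and N/2 - 1 after
  expect_false(any(ar$valid[c(1:8, 42:48)]))
  expect_true(all(ar$valid[9:41]))

  # stationary with zero jitter: every valid frame ST
  st <- analyze_trajectory(trajectory(1L, frame = 1:48, x_um = 5, dt = dt),
                           cfg, dt = dt)
  expect_true(all(st$state[st$valid] == "ST"))

  # pure zero-drift oscillation classifies DP at any tested amplitude
  for (d in c(0.2, 0.5, 2)) {
    dp <- analyze_trajectory(square_wave_traj(d = d, n = 48L, dt = dt),
                             cfg, dt = dt)
    expect_true(all(dp$state[dp$valid] == "DP"))
  }

  # shorter than the window: all invalid, with a warning
  expect_warning(short <- analyze_trajectory(line_traj(1, n = 10L, dt = dt),
                                             cfg, dt = dt),
                 "shorter than")
  expect_false(any(short$valid))
})

test_that("per-frame state accuracy is high away from transitions", {
  dt <- 1.5
  cfg <- pipeline_config()
  params <- motion_model_params()
  set.seed(41)
  correct <- 0L; total <- 0L
  for (k in 1:30) {
    states <- simulate_state_sequence(params, 200L)
    sim <- simulate_trajectory(states, params, dt, position_noise_sd = 0.05)
    series <- analyze_trajectory(sim$trajectory, cfg, dt = dt)
    trans <- which(diff(as.integer(factor(states))) != 0)
    far <- vapply(seq_along(states), function(i)
      !length(trans) || min(abs(i - trans)) >= 8L, TRUE)
    use <- series$valid & far
    correct <- correct + sum(series$state[use] == states[use])
    total <- total + sum(use)
  }
  expect_gt(correct / total, 0.9)
})

test_that("sustained speed is nearly unbiased under position noise", {
  dt <- 1.5; N <- 16L
  set.seed(51)
  speeds <- numeric(400L)
  for (k in seq_along(speeds)) {
    tr <- trajectory(1L, frame = 1:16,
                     x_um = 0.5 * dt * (0:15) + rnorm(16L, 0, 0.05), dt = dt)
    speeds[k] <- decompose_window(tr, 9L, N, dt)$sustained_signed_speed
  }
  expect_lt(abs(mean(speeds) - 0.5) / 0.5, 0.02)
})

test_that("threshold monotonicity holds for state proportions", {
  dt <- 1.5
  params <- motion_model_params()
  set.seed(61)
  series_at <- function(theta) {
    cfg <- pipeline_config(clustering_threshold_speed = theta)
    lapply(1:12, function(k) {
      states <- simulate_state_sequence(params, 120L, seed = 100 + k)
      sim <- simulate_trajectory(states, params, dt, seed = 200 + k,
                                 position_noise_sd = 0.05)
      analyze_trajectory(sim$trajectory, cfg, dt = dt)
    })
  }
  thetas <- c(0.01, 0.05, 0.2, 0.5)
  props <- t(vapply(thetas, function(th) state_proportions(series_at(th)),
                    numeric(4L)))
  expect_true(all(diff(props[, "ST"]) >= 0))
  expect_true(all(diff(props[, "AR"] + props[, "RR"]) <= 0))
})

test_that("ensemble state proportions aggregate correctly", {
  dt <- 1.5
  cfg <- pipeline_config()
  mk_series <- function(id, speed) {
    tr <- if (speed == 0) trajectory(id, frame = 1:32, x_um = 1, dt = dt)
          else trajectory(id, frame = 1:32,
                          x_um = speed * dt * (0:31), dt = dt)
    analyze_trajectory(tr, cfg, dt = dt)
  }
  # 3 AR + 1 RR: proportions 0.75 / 0.25 at every valid frame
  series <- c(lapply(1:3, mk_series, speed = 1), list(mk_series(4L, -1)))
  tab <- state_proportions_over_time(series)
  expect_true(all(tab$AR == 0.75))
  expect_true(all(tab$RR == 0.25))
  expect_true(all(abs(tab$ST + tab$DP + tab$AR + tab$RR - 1) < 1e-12))
  expect_equal(unique(tab$mean_run_speed), 1.0, tolerance = 1e-9)

  # all ST
  st_series <- lapply(1:4, mk_series, speed = 0)
  expect_true(all(state_proportions_over_time(st_series)$ST == 1))

  # simulated ensemble matches its designed stationary distribution
  params <- motion_model_params()
  target <- stationary_distribution(params$transition_matrix)
  set.seed(71)
  sims <- lapply(1:60, function(k) {
    states <- simulate_state_sequence(params, 150L)
    analyze_state <- analyze_trajectory(
      simulate_trajectory(states, params, dt,
                          position_noise_sd = 0.02)$trajectory, cfg, dt = dt)
    analyze_state
  })
  props <- state_proportions(sims)
  for (s in c("ST", "DP", "AR", "RR"))
    expect_lt(abs(props[[s]] - target[[s]]), 0.08)
})
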