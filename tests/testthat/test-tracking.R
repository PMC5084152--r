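# Independent plain Kalman filter used as the reduction oracle for the IMM.
oracle_kf <- function(z_list, F, Q, H, R, m0, P0) {
  m <- m0; P <- P0
  for (z in z_list) {
    m <- as.numeric(F %*% m); P <- F %*% P %*% t(F) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    m <- as.numeric(m + K %*% (z - H %*% m))
    IKH <- diag(length(m)) - K %*% H
    P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)
  }
  list(mean = m, cov = P)
}

test_that("single-model IMM reduces exactly to a plain Kalman filter", {
  dt <- 1.5
  st <- imm_init(c(0, 0, 0), intensity = 100,
                 models = list(motion_model("linear1")))
  mm <- mitotrack:::model_matrices(motion_model("linear1"), dt)
  m0 <- st$mean; P0 <- st$cov
  set.seed(31)
  zs <- lapply(1:100, function(i)
    c(i * 1.5 + rnorm(1, 0, 0.05), rnorm(1, 0, 0.05), rnorm(1, 0, 0.05),
      100 + rnorm(1)))
  for (z in zs) {
    st <- imm_predict(st, dt)
    st <- imm_update(st, z)
  }
  orc <- oracle_kf(zs, mm$F, mm$Q, st$H, st$R, m0, P0)
  expect_equal(st$mean, orc$mean, tolerance = 1e-12)
  expect_equal(st$cov, orc$cov, tolerance = 1e-12)
})

test_that("IMM predictions follow each model's kinematics exactly", {
  dt <- 1.5
  # constant-velocity model, no process noise: x advances by v dt exactly
  st <- imm_init(c(0, 0, 0), models = list(motion_model("linear1",
                                                        sigma_process = 0)))
  st$means[[1]][4] <- 1.0   # vx = 1 um/s
  pr <- imm_predict(st, dt)
  expect_equal(pr$mean[1], 1.5, tolerance = 1e-12)
  # random-walk model: position unchanged, covariance inflated by exactly Q
  st2 <- imm_init(c(2, 3, 4), models = list(motion_model("random",
                                                         sigma_process = 0.7)))
  cov0 <- st2$covs[[1]]
  pr2 <- imm_predict(st2, dt)
  expect_equal(pr2$mean[1:3], c(2, 3, 4), tolerance = 1e-12)
  expect_equal(diag(pr2$cov)[1:3] - diag(cov0)[1:3], rep(0.7^2 * dt, 3),
               tolerance = 1e-12)
})

test_that("model probabilities stay a simplex and select the right model", {
  dt <- 1.5
  run_filter <- function(positions, noise_sd = 0, seed = 1) {
    set.seed(seed)
    st <- imm_init(positions[1, ], intensity = 100, meas_sd_pos = 0.05)
    for (i in 2:nrow(positions)) {
      st <- imm_predict(st, dt)
      z <- positions[i, ] + rnorm(3, 0, noise_sd)
      st <- imm_update(st, c(z, 100))
      expect_equal(sum(st$mu), 1, tolerance = 1e-12)
      expect_true(all(st$mu >= 0))
    }
    st
  }
  # 50-frame noise-free constant-velocity track: linear1 wins
  pos_cv <- cbind(0.9 * dt * (0:49), 0, 0)
  st_cv <- run_filter(pos_cv)
  expect_gt(st_cv$mu[2], 0.5)
  # 50-frame stationary noisy track: random walk is the argmax
  set.seed(5)
  pos_st <- cbind(rnorm(50, 0, 0.05), rnorm(50, 0, 0.05), rnorm(50, 0, 0.05))
  st_st <- run_filter(pos_st, noise_sd = 0, seed = 2)
  expect_identical(which.max(st_st$mu), 1L)
})

test_that("equal-likelihood measurements leave model probabilities unchanged", {
  # all models share one state and prediction when process noise is equal and
  # the state is stationary at the origin with zero velocity
  st <- imm_init(c(0, 0, 0), intensity = 0,
                 models = list(motion_model("random", sigma_process = 0.3),
                               motion_model("random", sigma_process = 0.3),
                               motion_model("random", sigma_process = 0.3)),
                 mu0 = c(0.5, 0.3, 0.2), Pi = diag(3))
  pr <- imm_predict(st, 1.5)
  up <- imm_update(pr, c(0, 0, 0, 0))
  expect_equal(up$mu, c(0.5, 0.3, 0.2), tolerance = 1e-9)
})

test_that("assignment is globally optimal against exhaustive search", {
  set.seed(77)
  for (trial in 1:25) {
    n <- sample(3:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n, n)
    sol <- hungarian_assign(cost)
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- min(vapply(perms(seq_len(n)), function(p)
      sum(cost[cbind(seq_len(n), p)]), 0))
    expect_equal(sol$cost, best, tolerance = 1e-9)
  }
})

test_that("gating produces births and misses", {
  preds <- data.frame(x_um = 0, y_um = 0, z_um = 0)
  dets <- data.frame(x_um = 5, y_um = 0, z_um = 0)
  asg <- assign_detections(preds, dets, gate = 2)
  expect_identical(nrow(asg$matches), 0L)
  expect_identical(asg$births, 1L)
  expect_identical(asg$misses, 1L)
  # within the gate: matched
  asg2 <- assign_detections(preds, data.frame(x_um = 0.1, y_um = 0, z_um = 0),
                            gate = 2)
  expect_identical(nrow(asg2$matches), 1L)
})

test_that("build_tracks recovers noiseless well-separated simulated tracks", {
  md <- default_md(n_frames = 50L, n_z = 5L, height = 128L, width = 128L)
  ds <- generate_dataset(n_particles = 10L, n_frames = 50L, seed = 17,
                         metadata = md,
                         imaging = quiet_imaging(groove_spacing = 5))
  cfg <- pipeline_config()
  # detections straight from ground truth (tracker tested in isolation)
  dets <- lapply(seq_len(50L), function(f) {
    data.frame(frame = f,
               x_um = ds$truth$positions[, f, 1],
               y_um = ds$truth$positions[, f, 2],
               z_um = ds$truth$positions[, f, 3],
               volume_vox = 30L, total_intensity = 3000)
  })
  tracks <- build_tracks(dets, cfg, md)
  expect_identical(length(tracks), 10L)
  lens <- vapply(tracks, nrow, 0L)
  expect_true(all(lens == 50L))
  # each track matches one ground-truth particle within 0.5 voxel per frame
  for (tr in tracks) {
    d0 <- vapply(seq_len(10L), function(p)
      max(abs(tr$x_um - ds$truth$positions[p, , 1]) +
          abs(tr$y_um - ds$truth$positions[p, , 2])), 0)
    expect_lt(min(d0), 0.5 * md$pixel_size_xy)
  }
  # single detection in frame 1 only -> one 1-point track
  one <- build_tracks(list(data.frame(frame = 1L, x_um = 1, y_um = 1,
                                      z_um = 1, volume_vox = 10L,
                                      total_intensity = 100)), cfg, md)
  expect_identical(length(one), 1L)
  expect_identical(nrow(one[[1L]]), 1L)
})

test_that("intensity features preserve identity through a crossing", {
  md <- default_md(n_frames = 30L)
  dt <- 1.5
  # two particles crossing mid-sequence, intensity ratio 3:1
  xa <- 0 + 0.4 * dt * (0:29); xb <- 20 - 0.4 * dt * (0:29)
  dets <- lapply(1:30, function(f) data.frame(
    frame = f, x_um = c(xa[f], xb[f]), y_um = c(2, 2), z_um = c(2, 2),
    volume_vox = c(40L, 15L), total_intensity = c(3000, 1000)))
  tracks <- build_tracks(dets, pipeline_config(), md)
  expect_identical(length(tracks), 2L)
  ints <- lapply(tracks, function(tr) unique(tr$intensity))
  expect_true(all(vapply(ints, length, 0L) == 1L))  # no identity swap
})

test_that("link_and_trim merges dropouts and removes fragments", {
  dt <- 1.5
  # one constant-velocity track split by a 2-frame dropout
  t1 <- trajectory(1L, frame = 1:20, x_um = 0.5 * dt * (0:19), dt = dt)
  t2 <- trajectory(2L, frame = 23:40, x_um = 0.5 * dt * (22:39), dt = dt)
  merged <- link_and_trim(list(t1, t2), max_link_gap = 3L,
                          max_link_dist = 1.0, min_length = 8L, dt = dt)
  expect_identical(length(merged), 1L)
  expect_identical(merged[[1L]]$frame, 1:40)
  expect_true(all(merged[[1L]]$interpolated[21:22]))
  expect_false(any(merged[[1L]]$interpolated[c(1:20, 23:40)]))
  # interpolated positions lie on the line
  expect_equal(merged[[1L]]$x_um[21:22], 0.5 * dt * c(20, 21),
               tolerance = 1e-9)

  # short track with no partner is removed
  short <- trajectory(3L, frame = 1:7, x_um = 1:7, dt = dt)
  expect_identical(length(link_and_trim(list(short), min_length = 8L,
                                        dt = dt)), 0L)
  # disjoint far-apart tracks unchanged
  a <- trajectory(1L, frame = 1:10, x_um = 1:10, dt = dt)
  b <- trajectory(2L, frame = 1:10, x_um = 100 + 1:10, dt = dt)
  kept <- link_and_trim(list(a, b), min_length = 8L, dt = dt)
  expect_identical(length(kept), 2L)
})
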