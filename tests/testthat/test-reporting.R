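test_that("max projection equals the brute-force per-pixel maximum", {
  set.seed(9)
  md <- default_md(n_frames = 3L, n_z = 4L, height = 6L, width = 7L)
  arr <- array(runif(3 * 4 * 6 * 7), c(3, 4, 6, 7))
  seq0 <- image_sequence_4d(arr, md)
  proj <- max_project_z(seq0)
  for (t in 1:3) for (y in 1:6) for (x in 1:7)
    expect_identical(proj[t, y, x], max(arr[t, , y, x]))
  # n_z = 1 is the identity
  md1 <- default_md(n_frames = 2L, n_z = 1L, height = 4L, width = 4L)
  arr1 <- array(runif(2 * 1 * 4 * 4), c(2, 1, 4, 4))
  expect_equal(max_project_z(image_sequence_4d(arr1, md1)),
               array(arr1[, 1L, , ], c(2, 4, 4)))
})

test_that("kymographs trace particle motion at the right slope", {
  dt <- 1.5; bin <- 0.2
  # stationary particle: one constant column
  st <- trajectory(1L, frame = 1:30, x_um = 5, dt = dt)
  ky <- kymograph(list(st), bin_um = bin, axis_length_um = 20)
  cols <- apply(ky$intensity, 1L, which.max)
  expect_identical(length(unique(cols)), 1L)
  # AR at 1 um/s: column drift per row = dt * 1 / bin_um
  ar <- line_traj(1.0, n = 30L, dt = dt)
  ky2 <- kymograph(list(ar), bin_um = bin, axis_length_um = 60)
  cols2 <- apply(ky2$intensity, 1L, which.max)
  # columns are integer bins: the drift per row averages dt * v / bin_um
  # (up to one bin of floor-quantisation across the whole trace)
  expect_lt(abs(mean(diff(cols2)) - dt * 1.0 / bin), 1 / 29 + 1e-9)
  expect_lte(max(abs(diff(cols2) - dt / bin)), 1)
  # DP particle: oscillating trace, zero mean drift
  params <- motion_model_params(axis_jitter_sd = 0)
  dp <- simulate_trajectory(rep("DP", 200L), params, dt, seed = 12,
                            origin = c(10, 0, 0))$trajectory
  ky3 <- kymograph(list(dp), bin_um = bin, axis_length_um = 20)
  cols3 <- apply(ky3$intensity, 1L, which.max)
  expect_lt(abs(mean(diff(cols3))), 0.05)
  expect_gt(stats::sd(cols3), 0)

  # image mode: a rendered stationary blob yields a fixed argmax column
  md <- default_md(n_frames = 3L, n_z = 3L, height = 16L, width = 32L)
  stack <- array(0, c(3, 3, 16, 32))
  for (t in 1:3)
    stack[t, , , ] <- render_frame(matrix(c(3, 1.6, 1), 1, 3),
                                   quiet_imaging(), md)
  kyi <- kymograph(image_sequence_4d(stack, md))
  ci <- apply(kyi$intensity, 1L, which.max)
  expect_identical(length(unique(ci)), 1L)
  expect_equal((unique(ci) - 1L) * kyi$bin_um, 3, tolerance = 0.2)
})

test_that("log-normal speed fits recover known parameters", {
  set.seed(14)
  x <- stats::rlnorm(1e4, meanlog = log(0.5), sdlog = 0.4)
  fit <- fit_speed_distribution(x, "sustained")
  expect_lt(abs(fit$parameters[["meanlog"]] - log(0.5)) / abs(log(0.5)), 0.05)
  expect_lt(abs(fit$parameters[["sdlog"]] - 0.4) / 0.4, 0.05)
  # fitted curve integrates to ~1 over its support
  xs <- seq(1e-4, 10, length.out = 20000L)
  integral <- sum(diff(xs) * (fit$pdf(xs)[-1L] + fit$pdf(xs)[-20000L]) / 2)
  expect_gt(integral, 0.99); expect_lt(integral, 1.01)
  # histogram densities integrate to 1
  widths <- diff(fit$breaks)
  expect_equal(sum(widths * fit$density), 1, tolerance = 1e-6)
  # degenerate input errors
  expect_error(fit_speed_distribution(rep(0.3, 100)), "degenerate")
  expect_error(fit_speed_distribution(stats::runif(10)), "at least 50")
})

test_that("intersection threshold matches the analytic crossing", {
  set.seed(15)
  # equal sdlog log-normals cross at exp((m1 + m2) / 2) exactly
  m1 <- log(0.02); m2 <- log(0.5); s <- 0.6
  a <- fit_speed_distribution(stats::rlnorm(2e4, m1, s))
  b <- fit_speed_distribution(stats::rlnorm(2e4, m2, s))
  analytic <- exp((a$parameters[["meanlog"]] + b$parameters[["meanlog"]]) / 2)
  found <- find_intersection_threshold(a, b)
  expect_lt(abs(found - analytic), 1e-3)
  # identical distributions: no sign change
  expect_error(find_intersection_threshold(a, a), "no intersection")
})

test_that("simulated slow/fast conditions cross between their mode speeds", {
  make_transients <- function(amplitude, seed) {
    params <- motion_model_params(dp_oscillation_amplitude = amplitude,
                                  axis_jitter_sd = 0)
    # an ensemble of trajectories per condition, as in a real experiment
    unlist(lapply(1:5, function(k) {
      sim <- simulate_trajectory(rep("DP", 400L), params, dt = 1.5,
                                 seed = seed * 31 + k,
                                 position_noise_sd = 0.02)
      series <- analyze_trajectory(sim$trajectory, pipeline_config(), dt = 1.5)
      series$transient_speed[series$valid]
    }))
  }
  crossings <- vapply(1:10, function(s) {
    slow <- fit_speed_distribution(make_transients(0.03, seed = s))
    fast <- fit_speed_distribution(make_transients(0.75, seed = 100 + s))
    find_intersection_threshold(slow, fast)
  }, 0)
  expect_true(all(crossings > 0.02 & crossings < 0.5))
  expect_lt(stats::sd(crossings) / mean(crossings), 0.10)
})

test_that("group summaries replicate at the sequence level", {
  dt <- 1.5; cfg <- pipeline_config()
  mk_series <- function(speed, n = 32L) {
    tr <- if (speed == 0) trajectory(1L, frame = 1:n, x_um = 1, dt = dt)
          else line_traj(speed, n = n, dt = dt)
    analyze_trajectory(tr, cfg, dt = dt)
  }
  all_st <- list(list(mk_series(0), mk_series(0)))
  tab <- summarize_groups(list(still = all_st))
  expect_equal(tab$ST_mean, 1); expect_equal(tab$ST_sd, 0)

  # two identical groups -> identical rows (apart from the label)
  g <- list(list(mk_series(1), mk_series(0)))
  tab2 <- summarize_groups(list(a = g, b = g))
  expect_equal(tab2$ST_mean[1], tab2$ST_mean[2])
  expect_equal(tab2$run_speed_mean[1], tab2$run_speed_mean[2])
  expect_error(summarize_groups(list(a = list())), "empty group")

  # warm/cold transition presets order ST proportion as designed
  cold_m <- default_transition_matrix()
  cold_m["ST", ] <- c(0.998, 0.002, 0, 0)      # nearly frozen
  warm <- motion_model_params()
  cold <- motion_model_params(transition_matrix = cold_m)
  seq_series <- function(params, seed) {
    lapply(1:15, function(k) {
      st <- simulate_state_sequence(params, 120L, seed = seed * 1000 + k)
      sim <- simulate_trajectory(st, params, dt, seed = seed * 2000 + k,
                                 position_noise_sd = 0.02)
      analyze_trajectory(sim$trajectory, cfg, dt = dt)
    })
  }
  tab3 <- summarize_groups(list(
    warm = lapply(1:3, function(s) seq_series(warm, s)),
    cold = lapply(1:3, function(s) seq_series(cold, 10 + s))))
  expect_gt(tab3$ST_mean[tab3$group == "cold"],
            tab3$ST_mean[tab3$group == "warm"])
})
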