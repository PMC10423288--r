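test_that("gaussian smoothing preserves constants and reduces white noise by the kernel gain", {
  rc <- pearlrot:::new_sensor_recording(0:199, matrix(5, 200L, 2L), NULL)
  expect_lt(max(abs(gaussian_smooth(rc)$values - 5)), 1e-12)
  expect_identical(gaussian_smooth(rc, window = 1L), rc)

  wts <- gaussian_kernel(60L)
  expect_equal(sum(wts), 1, tolerance = 1e-12)
  gain <- sqrt(sum(wts^2))
  set.seed(1)
  x <- matrix(stats::rnorm(40000), ncol = 1L)
  rec <- pearlrot:::new_sensor_recording(seq_len(nrow(x)) - 1, x, NULL)
  sm <- gaussian_smooth(rec)$values[200:39800, 1L] # interior, edge-free
  expect_equal(stats::sd(sm) / 1, gain, tolerance = 0.1)

  expect_error(gaussian_smooth(rc, window = 500L), "exceeds")
})

test_that("reconstruction recovers a zenith reading and is odd in the channels", {
  z <- build_dome(per_ring = 1L, ring_angles = 90, axis_dir = "outward")
  rec <- pearlrot:::new_sensor_recording(0:4, matrix(2, 5L, 1L), z)
  tr <- reconstruct_orientation(rec)
  expect_equal(tr$u[1L, ], c(0, 0, 1), tolerance = 1e-12)
  rec_neg <- pearlrot:::new_sensor_recording(0:4, matrix(-2, 5L, 1L), z)
  expect_equal(reconstruct_orientation(rec_neg)$u[1L, ], c(0, 0, -1),
               tolerance = 1e-12)
})

test_that("a dense full-sphere radial grid recovers a static dipole to < 0.5 degrees", {
  grid <- sphere_sensor_grid(1000)
  set.seed(42)
  for (i in 1:5) {
    m <- pearlrot:::random_unit()
    tr <- static_traj(m, n = 2L, magnet_position = c(0, 0, 0))
    rec <- simulate_recording(tr, grid, noise_sd = 0, offset_sd = 0)
    u <- reconstruct_orientation(rec)$u[1L, ]
    expect_lt(pearlrot:::angle_between(u, m), 0.5)
  }
})

test_that("dome reconstruction bias is bounded and shrinks with sensor count", {
  dome25 <- build_dome()
  dome1k <- sphere_sensor_grid(1000, hemisphere = TRUE, axis_dir = "inward")
  traj <- simulate_trajectory("Round", duration = 2 * 3600, rate = 1 / 60,
                              speed = 6, seed = 13)
  err <- function(geom) {
    rec <- simulate_recording(traj, geom, noise_sd = 0, offset_sd = 0)
    est <- reconstruct_orientation(rec)
    stats::median(pearlrot:::angle_between(est$u, traj$u))
  }
  e25 <- err(dome25)
  e1k <- err(dome1k)
  expect_lt(e25, 10)
  expect_lt(e1k, e25)
})

test_that("smoothing and reconstruction commute on noiseless data", {
  geom <- build_dome()
  sc <- simulate_clock_scene("perpendicular", 2, 1800)
  rec <- simulate_recording(sc$trajectory, geom, noise_sd = 0, offset_sd = 0)
  # both operations are linear up to the final normalization
  r1 <- reconstruct_orientation(gaussian_smooth(rec), geom)
  phat <- position_weights(geom)
  W <- phat * rowSums(geom$axes * phat)
  raw <- rec$values %*% W
  wts <- gaussian_kernel(60L)
  raw_sm <- pearlrot:::smooth_channel_matrix(raw, wts, attr(wts, "offsets"))
  ang <- pearlrot:::angle_between(r1$u, raw_sm / sqrt(rowSums(raw_sm^2)))
  expect_lt(max(ang) * pi / 180, 1e-6) # within a microradian
})

test_that("equator projection wraps azimuths and masks the poles", {
  tr <- orientation_trajectory(0:3, rbind(
    c(1, 0, 0), c(0, -1, 0), c(0, 0, 1), c(0.6, 0, 0.8)))
  az <- project_equator(tr)
  expect_equal(az$phi[1:2], c(0, 270))
  expect_false(az$valid[3L])
  expect_true(az$valid[4L])
  # steady clock rotation: azimuth advances 6 deg/min between steps
  sc <- simulate_clock_scene("perpendicular", 2, 600)
  azs <- project_equator(sc$trajectory)
  rate <- pearlrot:::wrap180(diff(azs$phi)) * 60 # deg/min at 1 Hz
  expect_lt(max(abs(rate - 6)), 1e-6)
})

test_that("angular speed estimators agree with closed-form kinematics", {
  expect_equal(angular_speed(static_traj(n = 20L))$mean, 0)
  expect_error(angular_speed(static_traj(n = 1L)), "two timestamps")

  sc <- simulate_clock_scene("perpendicular", 2, 3600)
  est <- angular_speed(sc$trajectory)
  expect_equal(est$mean, 6, tolerance = 1e-9)
  expect_equal(est$hours_per_rev, 1, tolerance = 1e-9)

  slow <- rotation_traj(duration = 3600, speed = 0.69)
  est2 <- angular_speed(slow)
  expect_equal(est2$hours_per_rev, 360 / (est2$mean * 60), tolerance = 1e-12)
  expect_equal(est2$hours_per_rev, 8.70, tolerance = 1e-2)
})

test_that("lagged steps recover the speed of noisy filtered recordings", {
  geom <- build_dome()
  traj <- simulate_trajectory("Atypical", duration = 6 * 3600, rate = 1,
                              speed = 0.69, axis = c(0, 0, 1),
                              u0 = c(1, 0, 0), jitter = 0, seed = 2)
  rec <- simulate_recording(traj, geom, noise_frac = 0.05, offset_frac = 0.01,
                            seed = 3)
  tr <- reconstruct_orientation(gaussian_smooth(rec), geom)
  est <- angular_speed(tr, lag = 120L)
  expect_lt(abs(est$mean - 0.69) / 0.69, 0.05)
})

test_that("calibration accuracy scores scenes against the clock speed", {
  expect_equal(calibration_accuracy(6, 6), 100)
  expect_equal(calibration_accuracy(0, 6), 0)
  expect_equal(calibration_accuracy(12, 6), 0) # clamped at zero
  expect_equal(calibration_accuracy(c(6, 5.7, 6.3), 6),
               mean(c(100, 95, 95)))
  expect_error(calibration_accuracy(1, 0), "positive")
})

test_that("observability separates rotation from stillness", {
  expect_equal(observability_score(static_traj(n = 50L)), 0)
  rot <- rotation_traj(duration = 600, speed = 6)
  expect_equal(observability_score(rot), 1)
})

test_that("binned kinematics produce 2 x bins features with sane values", {
  tr <- rotation_traj(duration = 86400, rate = 1 / 60, speed = 0.69)
  f <- binned_kinematics(tr, bins_per_day = 100L)
  expect_length(f, 200L)
  expect_lt(max(abs(f[101:200])), 1e-9) # constant speed: zero acceleration
  expect_equal(unname(f[1L]), 0.69, tolerance = 1e-6)

  base <- simulate_trajectory("Round", duration = 86400, rate = 1 / 60,
                              speed = 0.69, seed = 5)
  ev <- inject_rejection_event(base, onset = 18 * 3600, peak_speed = 4.8,
                               ramp_s = 1800, seed = 6)
  fe <- binned_kinematics(ev, bins_per_day = 100L)
  expect_equal(unname(fe[100L]), 4.8, tolerance = 0.15)
  expect_error(binned_kinematics(static_traj(n = 2L)), "too short")
})
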