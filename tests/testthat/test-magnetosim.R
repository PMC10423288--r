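test_that("dipole field matches the closed-form axial and equatorial cases", {
  d <- 0.2
  expect_equal(dipole_field(c(0, 0, 1), at = c(0, 0, d)),
               c(0, 0, 2 / d^3), tolerance = 1e-12)
  expect_equal(dipole_field(c(0, 0, 1), at = c(d, 0, 0)),
               c(0, 0, -1 / d^3), tolerance = 1e-12)
  # linearity: flipping the moment negates the field everywhere
  at <- c(0.11, -0.04, 0.07)
  expect_equal(dipole_field(c(1, 2, -1), at),
               -dipole_field(-c(1, 2, -1), at), tolerance = 1e-12)
  expect_equal(dipole_field(2 * c(1, 0, 1), at),
               2 * dipole_field(c(1, 0, 1), at), tolerance = 1e-12)
  expect_error(dipole_field(c(0, 0, 1), at = c(0, 0, 0)), "coincides")
})

test_that("Other regime is static up to a slow wobble", {
  tr0 <- simulate_trajectory("Other", duration = 600, jitter = 0, seed = 1)
  expect_equal(max(abs(sweep(tr0$u, 2L, tr0$u[1L, ]))), 0)
  # acos() conditioning near 1 leaves ~1e-4 deg/min of numerical residue
  expect_lt(angular_speed(tr0)$mean, 1e-3)
  tr <- simulate_trajectory("Other", duration = 3600, seed = 2)
  expect_lt(angular_speed(tr)$mean, 0.05) # deg/min
})

test_that("Atypical regime closes after one revolution and holds its speed", {
  tr <- simulate_trajectory("Atypical", duration = 3600, speed = 6,
                            axis = c(0, 0, 1), u0 = c(1, 0, 0), jitter = 0,
                            seed = 1)
  n <- nrow(tr$u)
  expect_lt(max(abs(tr$u[n, ] - tr$u[1L, ])), 1e-6)
  expect_equal(angular_speed(tr)$mean, 6, tolerance = 1e-9)
  # tilted start: per-step increments still average to the target speed
  tr2 <- simulate_trajectory("Atypical", duration = 7200, rate = 1 / 60,
                             speed = 0.69, seed = 7)
  expect_equal(angular_speed(tr2)$mean, 0.69, tolerance = 0.02)
})

test_that("Round regime tumbles at the target mean speed with unit norms", {
  tr <- simulate_trajectory("Round", duration = 7 * 86400, rate = 1 / 60,
                            speed = 0.69, seed = 3)
  expect_true(all(abs(sqrt(rowSums(tr$u^2)) - 1) < 1e-9))
  expect_equal(angular_speed(tr)$mean, 0.69, tolerance = 0.02)
  # tumbling axis disperses: weekly coverage far exceeds the Atypical ring
  expect_gt(stats::sd(tr$u[, 3]), 0.2)
})

test_that("trajectory generation is bit-reproducible under a fixed seed", {
  for (cl in c("Round", "Atypical", "Other")) {
    a <- simulate_trajectory(cl, duration = 1800, seed = 11)
    b <- simulate_trajectory(cl, duration = 1800, seed = 11)
    expect_identical(a$u, b$u)
  }
  expect_error(simulate_trajectory("Baroque", duration = 10), "arg")
})

test_that("clock scenes realize one revolution per hour in each mode", {
  geom <- build_dome()
  sc <- simulate_clock_scene("perpendicular", 2, 3600)
  az <- project_equator(sc$trajectory)
  expect_equal(sum(pearlrot:::wrap180(diff(az$phi))), 360, tolerance = 1e-9)
  expect_equal(sc$true_speed, 6)

  par <- simulate_clock_scene("parallel", 2, 3600)
  expect_lt(max(abs(sweep(par$trajectory$u, 2L, c(0, 0, 1)))), 1e-12)

  di <- simulate_clock_scene("diagonal", 2, 900)
  # 90-degree arc of a 45-degree cone
  expect_lt(max(abs(di$trajectory$u[, 3] - cos(pi / 4))), 1e-9)
  azd <- project_equator(di$trajectory)
  expect_equal(sum(pearlrot:::wrap180(diff(azd$phi))), 90, tolerance = 1e-9)

  # magnet sits on the dome axis at the height of the requested ring
  for (rp in 1:3) {
    mp <- simulate_clock_scene("perpendicular", rp, 60)$trajectory$magnet_position
    expect_equal(mp[3], geom$radius * sin(c(6, 30, 60)[rp] * pi / 180),
                 tolerance = 1e-12)
  }
  expect_error(simulate_clock_scene("perpendicular", 9, 60), "ring")
})

test_that("recordings are constant for static magnets and linear in the moment", {
  geom <- build_dome()
  tr <- static_traj(c(0.3, -0.5, 0.8), n = 50L)
  rec <- simulate_recording(tr, geom, noise_sd = 0, offset_sd = 0)
  expect_equal(dim(rec$values), c(50L, 25L))
  expect_true(all(apply(rec$values, 2L, function(x) max(abs(x - x[1L]))) < 1e-15))
  rec2 <- simulate_recording(tr, geom, noise_sd = 0, offset_sd = 0, moment = 2)
  expect_equal(rec2$values, 2 * rec$values, tolerance = 1e-12)
})

test_that("noiseless clock recordings are periodic with period 3600 s", {
  geom <- build_dome()
  sc <- simulate_clock_scene("perpendicular", 2, 7200)
  rec <- simulate_recording(sc$trajectory, geom, noise_sd = 0, offset_sd = 0)
  first <- rec$values[1:3600, ]
  second <- rec$values[3601:7200, ]
  expect_lt(max(abs(first - second)), 1e-9)
})

test_that("recording noise and offsets are seed-reproducible", {
  geom <- build_dome()
  tr <- static_traj(n = 30L)
  a <- simulate_recording(tr, geom, seed = 5)
  b <- simulate_recording(tr, geom, seed = 5)
  expect_identical(a$values, b$values)
  c_ <- simulate_recording(tr, geom, seed = 6)
  expect_false(identical(a$values, c_$values))
})

test_that("cohorts honour the class mix, metadata constraints and speed law", {
  expect_length(simulate_cohort(0), 0L)
  probs <- c(Round = 0.276, Atypical = 0.213, Other = 0.511)
  expect_equal(unname(round(47 * probs)), c(13, 10, 24))
  co <- simulate_cohort(40, acquisition_days = 0.02, rate = 1 / 60, seed = 9)
  md <- cohort_metadata(co)
  expect_true(all(md$culture_days >= md$acq_offset_days))
  expect_true(all(md$acq_offset_days >= 0))
  expect_true(all(md$speed[md$true_class == "Other"] == 0))
  expect_true(all(md$speed[md$true_class != "Other"] > 0))
  expect_setequal(unique(md$harvest_date_group), c("early", "mid", "late"))
  expect_error(simulate_cohort(5, class_probs = c(Round = 0.9, Atypical = 0.2,
                                                  Other = 0.1)), "sum to 1")
})

test_that("cohort speeds follow the truncated normal around 0.69", {
  co <- simulate_cohort(200, acquisition_days = 0.02, rate = 1 / 60, seed = 21)
  md <- cohort_metadata(co)
  sp <- md$speed[md$true_class != "Other"]
  expect_gt(length(sp), 50)
  expect_lt(abs(mean(sp) - 0.69), 3 * 0.13 / sqrt(length(sp)))
  expect_lt(abs(stats::sd(sp) - 0.13), 0.05)
})

test_that("rejection events ramp the speed and leave the past untouched", {
  tr <- simulate_trajectory("Round", duration = 6 * 3600, rate = 1 / 60,
                            speed = 0.69, seed = 4)
  expect_identical(inject_rejection_event(tr, onset = max(tr$t)), tr)
  onset <- 2 * 3600
  ev <- inject_rejection_event(tr, onset, peak_speed = 4.8, ramp_s = 3600,
                               seed = 8)
  pre <- tr$t <= onset
  expect_identical(ev$u[pre, ], tr$u[pre, ])
  # after the ramp completes, the walk runs at the peak speed
  plateau <- pearlrot:::traj_slice(ev, which(ev$t >= onset + 3600))
  expect_equal(angular_speed(plateau)$mean, 4.8, tolerance = 0.1)
  expect_error(inject_rejection_event(tr, onset = -5), "outside")
})
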