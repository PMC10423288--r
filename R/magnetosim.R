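# Synthetic-data generator: dipole physics, class-conditional rotation
# regimes, clock-calibration scenes, labeled cohorts with metadata.
#
# All angular rates are degrees per minute at the user surface; diffusion
# ("jitter") rates are degrees per sqrt-second. Field values are in arbitrary
# units (unit dipole prefactor): the sensor gain of the physical device is
# unknown and never needed, since the reconstruction only uses ratios.

#' Default magnet position in the dome
#'
#' The oyster sits on a base that centres the nucleus on the dome axis at the
#' height of the second sensor ring (30 degrees elevation).
#'
#' @param geom a dome `sensor_array`.
#' @return length-3 position in metres.
#' @export
default_magnet_position <- function(geom = build_dome()) {
  rings <- sort(unique(geom$ring[!is.na(geom$ring) & geom$ring < 90]))
  elev <- if (length(rings) >= 2L) rings[2L] else rings[1L]
  c(0, 0, geom$radius * sin(elev * DEG2RAD))
}

#' Magnetic dipole field
#'
#' Field of a point dipole with moment `moment` located at `position`,
#' evaluated at `at`, with unit prefactor (arbitrary field units):
#' B = (3 (m . rhat) rhat - m) / |r|^3. Linear in the moment.
#'
#' @param moment length-3 dipole moment (direction and magnitude).
#' @param at length-3 evaluation point (metres).
#' @param position length-3 dipole location (metres).
#' @return length-3 field vector.
#' @export
#' @examples
#' dipole_field(c(0, 0, 1), at = c(0, 0, 0.1)) # on-axis: (0, 0, 2/d^3)
dipole_field <- function(moment, at, position = c(0, 0, 0)) {
  r <- at - position
  d <- vec_norm(r)
  if (d == 0) stop("field evaluation point coincides with the dipole")
  rhat <- r / d
  (3 * sum(moment * rhat) * rhat - moment) / d^3
}

class_default_jitter <- function(shape_class) {
  # deg / sqrt(s): Round tumbling axis diffusion 30 deg/sqrt(h); Atypical
  # rotation-axis wander 2 deg/sqrt(h); Other residual wobble diffusion,
  # slow enough that apparent speed stays below 0.05 deg/min at 1 Hz.
  switch(shape_class,
    Round = 30 / 60,
    Atypical = 2 / 60,
    Other = 5e-4
  )
}

#' Simulate a class-conditional rotation trajectory
#'
#' Generates the magnet moment direction over time under one of the three
#' rotation regimes tied to the final pearl shape:
#' \describe{
#'   \item{Round}{great-circle random walk: each step rotates `u` by exactly
#'     `speed * dt` about a tangent axis that itself diffuses on the sphere at
#'     rate `jitter`, producing random tumbling.}
#'   \item{Atypical}{steady rotation about a nearly fixed axis (the axis
#'     diffuses slowly at rate `jitter`); the rotation rate is scaled by
#'     1/sin(angle to axis) so per-step angular increments equal
#'     `speed * dt`.}
#'   \item{Other}{no rotation: `u` performs a very slow diffusive wobble of
#'     magnitude `jitter` around its initial direction.}
#' }
#'
#' @param shape_class `"Round"`, `"Atypical"` or `"Other"`.
#' @param duration total duration in seconds.
#' @param rate sampling rate in Hz (1 Hz is the acquisition hardware rate).
#' @param speed target mean angular speed in degrees per minute (ignored for
#'   `"Other"`).
#' @param axis optional fixed initial rotation axis (unit 3-vector).
#' @param u0 optional initial moment direction.
#' @param jitter diffusion rate in degrees per sqrt-second; class-specific
#'   default, see Details.
#' @param magnet_position magnet location in dome coordinates.
#' @param seed RNG seed; identical arguments and seed give identical output.
#' @return an [orientation_trajectory()] with attributes `shape_class`,
#'   `speed`, `jitter`.
#' @export
simulate_trajectory <- function(shape_class = c("Round", "Atypical", "Other"),
                                duration, rate = 1, speed = 0.69,
                                axis = NULL, u0 = NULL, jitter = NULL,
                                magnet_position = default_magnet_position(),
                                seed = NULL) {
  shape_class <- match.arg(shape_class)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(rate, "rate", positive = TRUE)
  if (speed < 0) stop("`speed` must be >= 0")
  jitter <- jitter %||% class_default_jitter(shape_class)
  dt <- 1 / rate
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) * dt
  sp_step <- speed / 60 * dt # deg per step

  U <- with_seed(seed, {
    u <- if (is.null(u0)) random_unit() else normalize(u0)
    U <- matrix(0, n, 3L)
    U[1L, ] <- u
    jstep <- jitter * sqrt(dt)
    if (shape_class == "Other") {
      if (jitter == 0) {
        U[] <- rep(u, each = n)
      } else {
        raxes <- matrix(stats::rnorm(3L * (n - 1L)), ncol = 3L)
        rang <- stats::rnorm(n - 1L, 0, jstep)
        for (i in seq_len(n - 1L)) {
          u <- normalize(rotate_vec(u, normalize(raxes[i, ]), rang[i]))
          U[i + 1L, ] <- u
        }
      }
    } else {
      a <- if (is.null(axis)) {
        if (shape_class == "Round") random_tangent(u) else random_unit()
      } else normalize(axis)
      if (shape_class == "Atypical" && is.null(u0)) {
        # start at 60-90 degrees from the rotation axis (visible cone/ring)
        u <- normalize(rotate_vec(a, random_tangent(a), stats::runif(1, 60, 90)))
        U[1L, ] <- u
      }
      if (n > 1L) {
        raxes <- matrix(stats::rnorm(3L * (n - 1L)), ncol = 3L)
        rang <- stats::rnorm(n - 1L, 0, jstep)
        for (i in seq_len(n - 1L)) {
          if (jstep > 0) a <- rotate_vec(a, normalize(raxes[i, ]), rang[i])
          if (shape_class == "Round") {
            a <- a - sum(a * u) * u
            na <- vec_norm(a)
            a <- if (na < 1e-9) random_tangent(u) else a / na
            u <- normalize(rotate_vec(u, a, sp_step))
          } else {
            a <- normalize(a)
            st <- sqrt(max(0, 1 - sum(a * u)^2)) # sin(angle u, axis)
            u <- normalize(rotate_vec(u, a, sp_step / max(st, 0.105)))
          }
          U[i + 1L, ] <- u
        }
      }
    }
    U
  })

  traj <- orientation_trajectory(t, U, magnet_position = magnet_position)
  attr(traj, "shape_class") <- shape_class
  attr(traj, "speed") <- if (shape_class == "Other") 0 else speed
  attr(traj, "jitter") <- jitter
  traj
}

#' Simulate the clock-calibration scene
#'
#' A magnet on a clock-driven rod rotates about the vertical axis at exactly
#' one revolution per hour (6 degrees per minute). The magnet moment is
#' oriented parallel (0 degrees), diagonal (45) or perpendicular (90) to the
#' rotation axis, and the magnet is centred on the dome axis at the height of
#' the chosen sensor ring.
#'
#' @param magnet_mode `"parallel"`, `"diagonal"` or `"perpendicular"`.
#' @param ring_position which sensor ring (1, 2 or 3) sets the magnet height.
#' @param duration scene duration in seconds (one revolution = 3600 s).
#' @param rate sampling rate in Hz.
#' @param geom dome geometry.
#' @return list with `trajectory` (an [orientation_trajectory()]) and
#'   `true_speed` (6 deg/min).
#' @export
simulate_clock_scene <- function(magnet_mode = c("perpendicular", "diagonal",
                                                 "parallel"),
                                 ring_position = 2L, duration = 3600,
                                 rate = 1, geom = build_dome()) {
  magnet_mode <- match.arg(magnet_mode)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  rings <- sort(unique(geom$ring[!is.na(geom$ring) & geom$ring < 90]))
  if (!ring_position %in% seq_along(rings))
    stop("`ring_position` must index one of the sensor rings")
  tilt <- switch(magnet_mode, parallel = 0, diagonal = 45, perpendicular = 90)
  u0 <- c(sin(tilt * DEG2RAD), 0, cos(tilt * DEG2RAD))
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  U <- rotate_rows(matrix(u0, n, 3L, byrow = TRUE), c(0, 0, 1), 6 / 60 * t)
  mp <- c(0, 0, geom$radius * sin(rings[ring_position] * DEG2RAD))
  traj <- orientation_trajectory(t, U, magnet_position = mp)
  attr(traj, "shape_class") <- "clock"
  attr(traj, "speed") <- 6
  list(trajectory = traj, true_speed = 6)
}

new_sensor_recording <- function(t, values, geometry) {
  structure(list(t = as.numeric(t), values = values, geometry = geometry),
            class = "sensor_recording")
}

#' Forward-simulate the 25-channel magnetometer recording
#'
#' Projects the dipole field of the moving magnet onto each sensor's
#' measurement axis, then adds a per-channel constant offset (residual after
#' the hardware offset-compensation) and iid Gaussian noise. Noise levels
#' default to fractions of the RMS noiseless signal since field units are
#' arbitrary.
#'
#' @param traj an [orientation_trajectory()]; its `magnet_position` is used.
#' @param geom a `sensor_array`.
#' @param noise_sd,offset_sd absolute noise / offset standard deviations in
#'   field units; when `NULL` they default to `noise_frac` / `offset_frac`
#'   times the RMS noiseless signal.
#' @param noise_frac,offset_frac relative defaults (0.05 and 0.01).
#' @param moment dipole moment magnitude (readings are linear in it).
#' @param seed RNG seed; offsets are drawn once per channel, then the noise
#'   matrix, so output is bit-reproducible.
#' @return a `sensor_recording` with fields `t`, `values` (time x channels),
#'   `geometry`.
#' @export
simulate_recording <- function(traj, geom, noise_sd = NULL, offset_sd = NULL,
                               noise_frac = 0.05, offset_frac = 0.01,
                               moment = 1, seed = NULL) {
  stopifnot(inherits(traj, "orientation_trajectory"),
            inherits(geom, "sensor_array"))
  mp <- traj$magnet_position
  if (is.null(mp)) stop("trajectory carries no magnet position")
  R <- sweep(geom$positions, 2L, mp)
  d <- row_norms(R)
  if (any(d <= 0)) stop("magnet position coincides with a sensor")
  Rh <- R / d
  U <- traj$u
  A <- U %*% t(Rh)                       # (u . rhat) per time x sensor
  axproj <- rowSums(Rh * geom$axes)      # (rhat . axis) per sensor
  signal <- sweep(3 * A, 2L, axproj, "*") - U %*% t(geom$axes)
  signal <- moment * sweep(signal, 2L, d^3, "/")

  rms <- sqrt(mean(signal^2))
  noise_sd <- noise_sd %||% (noise_frac * rms)
  offset_sd <- offset_sd %||% (offset_frac * rms)
  k <- ncol(signal)
  values <- with_seed(seed, {
    off <- if (offset_sd > 0) stats::rnorm(k, 0, offset_sd) else numeric(k)
    out <- sweep(signal, 2L, off, "+")
    if (noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, noise_sd), nrow(out))
    out
  })
  new_sensor_recording(traj$t, values, geom)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d samples x %d channels, %.1f h span\n",
              length(x$t), ncol(x$values),
              (x$t[length(x$t)] - x$t[1L]) / 3600))
  invisible(x)
}

#' Write / read the recording CSV dialect (`t,s01..s25`)
#'
#' @param rec a `sensor_recording`.
#' @param path file path.
#' @param geometry optional `sensor_array` to attach on read.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  df <- data.frame(t = rec$t, rec$values)
  names(df) <- c("t", sprintf("s%02d", seq_len(ncol(rec$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path, geometry = NULL) {
  df <- utils::read.csv(path)
  new_sensor_recording(df$t, as.matrix(df[, -1L, drop = FALSE]), geometry)
}

#' Pearl shape classes
#'
#' Fixed class set and ordering used throughout the package.
#'
#' @return character vector `c("Other", "Atypical", "Round")`.
#' @export
pearl_classes <- function() c("Other", "Atypical", "Round")

new_pearl_record <- function(pearl_id, true_class, trajectory, culture_days,
                             acq_offset_days, harvest_date_group, speed) {
  stopifnot(culture_days >= acq_offset_days, acq_offset_days >= 0)
  structure(
    list(pearl_id = pearl_id, true_class = true_class,
         trajectory = trajectory, culture_days = culture_days,
         acq_offset_days = acq_offset_days,
         harvest_date_group = harvest_date_group, speed = speed),
    class = "pearl_record"
  )
}

#' Simulate a labeled cohort of monitored pearls
#'
#' Draws shape classes from `class_probs`, per-pearl rotation speeds from a
#' truncated normal (speeds do not differ by class: the regimes differ only
#' in rotation *pattern*), cultivation metadata, and one rotation trajectory
#' per pearl. `Other` pearls get zero rotation speed (wobble only).
#'
#' @param n_pearls cohort size.
#' @param class_probs named probabilities over [pearl_classes()] (any order);
#'   default is the observed shape mix (27.6% Round, 21.3% Atypical,
#'   51.1% Other).
#' @param speed_mean,speed_sd rotation-speed distribution in deg/min,
#'   truncated at zero.
#' @param culture_day_range integer range of days from graft to harvest.
#' @param acquisition_days length of the simulated acquisition per pearl, in
#'   days (may be fractional).
#' @param rate sampling rate in Hz.
#' @param min_offset_days earliest acquisition start after grafting (days).
#' @param seed RNG seed.
#' @return a `pearl_cohort`: list of `pearl_record`s.
#' @export
simulate_cohort <- function(n_pearls,
                            class_probs = c(Round = 0.276, Atypical = 0.213,
                                            Other = 0.511),
                            speed_mean = 0.69, speed_sd = 0.13,
                            culture_day_range = c(180L, 365L),
                            acquisition_days = 21, rate = 1 / 60,
                            min_offset_days = 14L, seed = NULL) {
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("`class_probs` must sum to 1")
  if (is.null(names(class_probs)) ||
      !setequal(names(class_probs), pearl_classes()))
    stop("`class_probs` must be named with the three pearl classes")
  if (n_pearls == 0L)
    return(structure(list(), class = "pearl_cohort"))
  if (culture_day_range[1L] < min_offset_days + ceiling(acquisition_days))
    stop("culture_day_range too short for the requested acquisition window")

  records <- with_seed(seed, {
    classes <- sample(names(class_probs), n_pearls, replace = TRUE,
                      prob = class_probs)
    speeds <- vapply(classes, function(cl) {
      if (cl == "Other") return(0)
      repeat {
        s <- stats::rnorm(1L, speed_mean, speed_sd)
        if (s > 0) return(s)
      }
    }, 0)
    culture <- sample(seq(culture_day_range[1L], culture_day_range[2L]),
                      n_pearls, replace = TRUE)
    offmax <- culture - ceiling(acquisition_days)
    offsets <- vapply(offmax, function(m)
      sample(seq(min_offset_days, m), 1L), 0L)
    traj_seeds <- sample.int(.Machine$integer.max - 1L, n_pearls)
    qs <- stats::quantile(culture, c(1 / 3, 2 / 3), type = 1L)
    groups <- cut(culture, c(-Inf, qs, Inf),
                  labels = c("early", "mid", "late"))
    lapply(seq_len(n_pearls), function(i) {
      traj <- simulate_trajectory(
        classes[i], duration = acquisition_days * 86400, rate = rate,
        speed = speeds[i], seed = traj_seeds[i]
      )
      new_pearl_record(sprintf("P%03d", i), classes[i], traj,
                       culture[i], offsets[i], as.character(groups[i]),
                       speeds[i])
    })
  })
  structure(records, class = "pearl_cohort")
}

#' @export
print.pearl_cohort <- function(x, ...) {
  cat(sprintf("<pearl_cohort> %d pearls\n", length(x)))
  if (length(x))
    print(table(vapply(x, `[[`, "", "true_class")))
  invisible(x)
}

#' Cohort metadata as a data frame
#'
#' @param cohort a `pearl_cohort`.
#' @return data frame with pearl_id, true_class, culture_days,
#'   acq_offset_days, harvest_date_group, speed.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "pearl_cohort"))
  do.call(rbind, lapply(cohort, function(r)
    data.frame(pearl_id = r$pearl_id, true_class = r$true_class,
               culture_days = r$culture_days,
               acq_offset_days = r$acq_offset_days,
               harvest_date_group = r$harvest_date_group,
               speed = r$speed)))
}

#' Inject a pre-rejection acceleration event
#'
#' After `onset`, the angular speed ramps linearly from the trajectory's base
#' speed to `peak_speed` over `ramp_s` seconds and stays there — the sudden
#' acceleration observed shortly before nucleus rejection. The pre-onset
#' segment is returned unchanged.
#'
#' @param traj an [orientation_trajectory()].
#' @param onset seconds since trajectory start.
#' @param peak_speed plateau speed in deg/min (default 4.8).
#' @param base_speed starting speed of the ramp; defaults to the trajectory's
#'   generator speed attribute.
#' @param ramp_s ramp duration in seconds.
#' @param jitter tangential axis diffusion of the post-onset walk
#'   (deg/sqrt-s).
#' @param seed RNG seed for the post-onset walk.
#' @return a new [orientation_trajectory()].
#' @export
inject_rejection_event <- function(traj, onset, peak_speed = 4.8,
                                   base_speed = NULL, ramp_s = 3600,
                                   jitter = 0.5, seed = NULL) {
  stopifnot(inherits(traj, "orientation_trajectory"))
  t0 <- traj$t[1L]
  tend <- traj$t[length(traj$t)]
  if (onset < t0 || onset > tend) stop("`onset` outside the trajectory")
  if (onset == tend) return(traj)
  base_speed <- base_speed %||% (attr(traj, "speed") %||% 0)

  pre <- traj$t <= onset
  npost <- sum(!pre)
  U <- traj$u
  idx_last <- max(which(pre))
  u <- U[idx_last, ]
  post_t <- traj$t[!pre]
  dt <- c(post_t[1L] - traj$t[idx_last], diff(post_t))
  sp <- base_speed + (peak_speed - base_speed) *
    pmin(1, (post_t - onset) / ramp_s) # deg/min at each post timestamp
  Upost <- with_seed(seed, {
    a <- random_tangent(u)
    raxes <- matrix(stats::rnorm(3L * npost), ncol = 3L)
    rang <- stats::rnorm(npost, 0, jitter * sqrt(mean(dt)))
    out <- matrix(0, npost, 3L)
    for (i in seq_len(npost)) {
      a <- rotate_vec(a, normalize(raxes[i, ]), rang[i])
      a <- a - sum(a * u) * u
      na <- vec_norm(a)
      a <- if (na < 1e-9) random_tangent(u) else a / na
      u <- normalize(rotate_vec(u, a, sp[i] / 60 * dt[i]))
      out[i, ] <- u
    }
    out
  })
  U[!pre, ] <- Upost
  out <- orientation_trajectory(traj$t, U,
                                magnet_position = traj$magnet_position,
                                valid = traj$valid)
  attr(out, "shape_class") <- attr(traj, "shape_class")
  attr(out, "speed") <- attr(traj, "speed")
  attr(out, "rejection_onset") <- onset
  out
}
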