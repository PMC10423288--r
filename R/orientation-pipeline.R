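# Signal path from raw 25-channel recordings to rotation statistics:
# Gaussian smoothing, orientation reconstruction, equator projection,
# angular-speed estimation, calibration accuracy, binned kinematic features.

#' Gaussian smoothing kernel
#'
#' Normalized Gaussian weights over a `window`-sample moving window. For even
#' windows the weights are centred between the two middle samples so the
#' kernel stays symmetric in value. The kernel SD defaults to `window / 5`
#' samples.
#'
#' @param window window length in samples.
#' @param sd kernel standard deviation in samples.
#' @return numeric weights summing to one, with attribute `offsets`.
#' @export
gaussian_kernel <- function(window = 60L, sd = window / 5) {
  if (window < 1L) stop("`window` must be >= 1")
  offsets <- seq(-(window %/% 2L), length.out = window)
  shift <- if (window %% 2L == 0L) 0.5 else 0
  w <- stats::dnorm(offsets + shift, 0, max(sd, 1e-12))
  w <- w / sum(w)
  attr(w, "offsets") <- offsets
  w
}

smooth_channel_matrix <- function(x, wts, offsets) {
  n <- nrow(x)
  m <- length(wts)
  idx <- seq_len(n) + m + offsets[1L] - 1L
  norm <- stats::convolve(rep(1, n), wts, type = "open")[idx]
  apply(x, 2L, function(col)
    stats::convolve(col, wts, type = "open")[idx] / norm)
}

#' Gaussian-weighted moving-average filter
#'
#' Smooths every channel of a recording with a Gaussian-weighted moving
#' average over a `window`-sample window (the device's standard noise filter).
#' Edges are handled by renormalizing the truncated window, so constant
#' channels pass through unchanged and output length equals input length.
#'
#' @param rec a `sensor_recording`.
#' @param window window length in samples (default 60).
#' @param sd kernel SD in samples (default `window / 5`).
#' @return a smoothed `sensor_recording`.
#' @export
gaussian_smooth <- function(rec, window = 60L, sd = window / 5) {
  stopifnot(inherits(rec, "sensor_recording"))
  n <- length(rec$t)
  if (n == 0L) stop("empty recording")
  if (window > n) stop("`window` exceeds the series length")
  if (window == 1L) return(rec)
  wts <- gaussian_kernel(window, sd)
  sm <- smooth_channel_matrix(rec$values, wts, attr(wts, "offsets"))
  new_sensor_recording(rec$t, sm, rec$geometry)
}

#' Reconstruct the magnet orientation from sensor channels
#'
#' The device's estimator: each channel value is converted to a radial field
#' reading (multiplied by the cosine between its measurement axis and its
#' unit position vector), weighted by the sensor's unit position vector and
#' summed; the summed vector is normalized into the moment direction
#' estimate. For a dense uniform radial grid this sum is parallel to the true
#' moment by symmetry; on the 25-sensor dome it carries a bounded bias.
#'
#' Frames whose raw vector norm falls below `floor_frac` times the trajectory
#' median norm (or is exactly zero) are flagged unreliable, not interpolated.
#'
#' @param rec a `sensor_recording`.
#' @param geom a `sensor_array`; defaults to the recording's geometry.
#' @param floor_frac low-norm flagging threshold (fraction of median norm).
#' @return an [orientation_trajectory()] with a `valid` mask and a
#'   `raw_norm` attribute.
#' @export
reconstruct_orientation <- function(rec, geom = NULL, floor_frac = 0.01) {
  stopifnot(inherits(rec, "sensor_recording"))
  geom <- geom %||% rec$geometry
  if (is.null(geom)) stop("no geometry available")
  if (ncol(rec$values) != length(geom$index))
    stop("channel count does not match the sensor array")
  phat <- position_weights(geom)
  axial <- rowSums(geom$axes * phat)       # cos(axis, radial) per sensor
  W <- phat * axial                        # rows: (axis . phat) * phat
  raw <- rec$values %*% W
  nrm <- row_norms(raw)
  med <- stats::median(nrm)
  valid <- nrm > max(floor_frac * med, 0)
  u <- raw
  ok <- nrm > 0
  u[ok, ] <- raw[ok, , drop = FALSE] / nrm[ok]
  u[!ok, ] <- NA_real_
  traj <- orientation_trajectory(rec$t, u, magnet_position = NULL,
                                 valid = valid)
  attr(traj, "raw_norm") <- nrm
  traj
}

#' Project a trajectory on the equator
#'
#' Reduces the moment direction to its azimuth angle (degrees in \[0, 360)),
#' the projection used to measure the real rotation of the pearl. Timestamps
#' too close to the poles (|z| > `pole_cut`) are flagged invalid, since the
#' azimuth is ill-conditioned there.
#'
#' @param traj an [orientation_trajectory()].
#' @param pole_cut |z| threshold above which frames are flagged.
#' @return an `azimuth_trajectory`: list with `t`, `phi`, `valid`.
#' @export
project_equator <- function(traj, pole_cut = 0.95) {
  stopifnot(inherits(traj, "orientation_trajectory"))
  phi <- wrap360(atan2(traj$u[, 2L], traj$u[, 1L]) * RAD2DEG)
  valid <- traj$valid & !is.na(traj$u[, 3L]) & abs(traj$u[, 3L]) <= pole_cut
  structure(list(t = traj$t, phi = phi, valid = valid),
            class = "azimuth_trajectory")
}

new_speed_estimate <- function(per_step, mean, sd, method, lag_s) {
  structure(
    list(per_step = per_step, mean = mean, sd = sd,
         hours_per_rev = if (is.finite(mean) && mean > 0)
           360 / (mean * 60) else Inf,
         method = method, lag_s = lag_s),
    class = "speed_estimate"
  )
}

#' Estimate the angular rotation speed
#'
#' Two estimators of the mean rotation speed in degrees per minute:
#' \describe{
#'   \item{step}{3D step angle `acos(u_t . u_(t+lag))` per elapsed time.
#'     With `lag = 1` this is the consecutive-sample definition; residual
#'     sensor noise inflates it, so for filtered noisy data a lag well beyond
#'     the smoothing kernel support (e.g. 120 s) is recommended.}
#'   \item{azimuth}{net signed azimuth displacement per elapsed time from the
#'     equator projection. Telescoping makes it exact for steady rotation
#'     about the vertical axis regardless of reconstruction bias.}
#' }
#'
#' @param traj an [orientation_trajectory()].
#' @param method `"step"` or `"azimuth"`.
#' @param lag step lag in *samples* for the step method.
#' @param pole_cut passed to [project_equator()] for the azimuth method.
#' @return a `speed_estimate`: `per_step` (deg/min series), `mean`, `sd`,
#'   `hours_per_rev` (= 360 / (60 mean)), `method`, `lag_s`.
#' @export
angular_speed <- function(traj, method = c("step", "azimuth"), lag = 1L,
                          pole_cut = 0.95) {
  stopifnot(inherits(traj, "orientation_trajectory"))
  method <- match.arg(method)
  n <- length(traj$t)
  if (n < 2L) stop("need at least two timestamps")
  lag <- max(1L, as.integer(lag))
  if (lag >= n) stop("`lag` must be smaller than the series length")

  if (method == "step") {
    i1 <- seq_len(n - lag)
    i2 <- i1 + lag
    ok <- traj$valid[i1] & traj$valid[i2] &
      !is.na(traj$u[i1, 1L]) & !is.na(traj$u[i2, 1L])
    ang <- angle_between(traj$u[i1[ok], , drop = FALSE],
                         traj$u[i2[ok], , drop = FALSE])
    dmin <- (traj$t[i2[ok]] - traj$t[i1[ok]]) / 60
    per_step <- ang / dmin
    mu <- mean(per_step)
    lag_s <- stats::median(traj$t[i2] - traj$t[i1])
  } else {
    az <- project_equator(traj, pole_cut)
    keep <- which(az$valid)
    if (length(keep) < 2L) stop("too few valid frames for azimuth speed")
    dphi <- wrap180(diff(az$phi[keep]))
    dmin <- diff(az$t[keep]) / 60
    per_step <- dphi / dmin
    mu <- abs(sum(dphi)) / sum(dmin)
    lag_s <- stats::median(diff(az$t[keep]))
  }
  new_speed_estimate(per_step, mu, stats::sd(per_step), method, lag_s)
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf(
    "<speed_estimate> %.3f deg/min (sd %.3f), %.2f h/rev [%s, lag %.0f s]\n",
    x$mean, x$sd, x$hours_per_rev, x$method, x$lag_s))
  invisible(x)
}

#' Serialize a speed estimate to JSON
#'
#' @param est a `speed_estimate`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @export
speed_estimate_to_json <- function(est, path = NULL) {
  stopifnot(inherits(est, "speed_estimate"))
  obj <- list(mean = est$mean, sd = est$sd,
              hours_per_rev = est$hours_per_rev, method = est$method,
              lag_s = est$lag_s)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Calibration accuracy against a known rotation speed
#'
#' Accuracy of a set of speed estimates against the clock rig's true speed,
#' `100 * max(0, 1 - |est - true| / true)` per scene, averaged over scenes
#' (the rig is run with the magnet parallel, diagonal and perpendicular to
#' the rotation axis and the three orientations are averaged).
#'
#' @param estimates numeric vector of mean speeds (deg/min), or a list of
#'   `speed_estimate`s, one per scene.
#' @param true_speed true rotation speed in deg/min (> 0).
#' @return accuracy percentage in \[0, 100\].
#' @export
calibration_accuracy <- function(estimates, true_speed) {
  stopifnot_scalar_number(true_speed, "true_speed", positive = TRUE)
  if (inherits(estimates, "speed_estimate")) estimates <- list(estimates)
  if (is.list(estimates))
    estimates <- vapply(estimates, function(e) {
      if (inherits(e, "speed_estimate")) e$mean else as.numeric(e)
    }, 0)
  mean(100 * pmax(0, 1 - abs(estimates - true_speed) / true_speed))
}

#' Observability score of a trajectory
#'
#' Fraction of steps whose angular increment exceeds a noise floor. Rotation
#' about the magnet's own axis is indistinguishable from immobility in the
#' sensor data; a low score marks trajectories whose apparent stillness may
#' be an unobservable axial rotation.
#'
#' @param traj an [orientation_trajectory()].
#' @param noise_floor_deg per-step angular threshold in degrees.
#' @return fraction in \[0, 1\].
#' @export
observability_score <- function(traj, noise_floor_deg = 0.05) {
  n <- length(traj$t)
  if (n < 2L) return(0)
  ok <- traj$valid[-n] & traj$valid[-1L]
  ang <- angle_between(traj$u[which(ok), , drop = FALSE],
                       traj$u[which(ok) + 1L, , drop = FALSE])
  if (!length(ang)) return(0)
  mean(ang > noise_floor_deg)
}

#' Binned kinematic features (legacy feature-vector approach)
#'
#' Per-bin mean angular velocity and acceleration over uniform time bins
#' (`bins_per_day` bins per day of data), concatenated — the feature vector
#' of the first, non-image classification attempt.
#'
#' @param traj an [orientation_trajectory()].
#' @param bins_per_day bins per 24 h of data.
#' @return named numeric vector of `2 * n_bins` features (velocity in
#'   deg/min, then acceleration in deg/min^2).
#' @export
binned_kinematics <- function(traj, bins_per_day = 100L) {
  stopifnot(inherits(traj, "orientation_trajectory"))
  n <- length(traj$t)
  if (n < 3L) stop("trajectory too short for kinematic features")
  span_days <- traj_duration(traj) / 86400
  n_bins <- max(1L, round(span_days * bins_per_day))

  i1 <- seq_len(n - 1L)
  ang <- angle_between(traj$u[i1, , drop = FALSE],
                       traj$u[i1 + 1L, , drop = FALSE])
  dmin <- diff(traj$t) / 60
  vel <- ang / dmin
  tm <- (traj$t[i1] + traj$t[i1 + 1L]) / 2

  acc <- diff(vel) / diff(tm / 60)           # deg/min^2
  ta <- (tm[-1L] + tm[-length(tm)]) / 2

  edges <- seq(traj$t[1L], traj$t[n], length.out = n_bins + 1L)
  bin_mean <- function(vals, times) {
    b <- pmin(n_bins, pmax(1L, findInterval(times, edges, rightmost.closed = TRUE)))
    out <- rep(0, n_bins)
    agg <- tapply(vals, b, mean)
    out[as.integer(names(agg))] <- agg
    out
  }
  feats <- c(bin_mean(vel, tm), bin_mean(acc, ta))
  names(feats) <- c(sprintf("v%03d", seq_len(n_bins)),
                    sprintf("a%03d", seq_len(n_bins)))
  feats
}
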