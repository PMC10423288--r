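# Sensor-array geometry: the hemispherical monitoring dome and dense
# reference grids used as reconstruction oracles.

#' Dome radius from enclosed volume
#'
#' Solves (2/3) pi r^3 = V for the radius of a hemispherical dome of volume
#' `volume_l` litres. The default 4.2 L dome gives r ~ 0.126 m.
#'
#' @param volume_l dome volume in litres.
#' @return radius in metres.
#' @export
#' @examples
#' dome_radius_from_volume(4.2)
dome_radius_from_volume <- function(volume_l = 4.2) {
  stopifnot_scalar_number(volume_l, "volume_l", positive = TRUE)
  (3 * volume_l * 1e-3 / (2 * pi))^(1 / 3)
}

new_sensor_array <- function(radius, positions, axes, ring, subclass = character()) {
  structure(
    list(
      radius = radius,
      index = seq_len(nrow(positions)),
      positions = positions,
      axes = axes,
      ring = ring
    ),
    class = c(subclass, "sensor_array")
  )
}

#' Build the hemispherical sensor dome
#'
#' Places single-axis magnetic sensors on the surface of a hemispherical dome
#' (base plane z = 0, zenith +z). Sensors sit on horizontal rings at the given
#' elevation angles, equally spaced in azimuth with the azimuth origin at +x,
#' plus one sensor at the zenith when a 90 degree ring with a single sensor is
#' requested. The default layout is the monitoring dome: rings of 8 sensors at
#' 6, 30 and 60 degrees elevation plus the zenith sensor, 25 sensors in all.
#'
#' Each sensor measures the field component along its axis; by default the
#' axis points inward at the dome centre (`axis_dir = "inward"`), the way
#' sensors glued to the dome face the oyster.
#'
#' @param radius dome radius in metres; default derives from the 4.2 L volume.
#' @param per_ring integer vector, sensors per ring.
#' @param ring_angles elevation angle of each ring in degrees, strictly
#'   increasing within \[0, 90\].
#' @param axis_dir `"inward"` (default) or `"outward"` radial measurement axes.
#' @return a `sensor_array` (subclass `pearl_dome`) with fields `radius`,
#'   `index`, `positions` (n x 3, metres), `axes` (n x 3 unit rows), `ring`
#'   (elevation in degrees).
#' @export
#' @examples
#' geom <- build_dome()
#' nrow(geom$positions) # 25
build_dome <- function(radius = dome_radius_from_volume(4.2),
                       per_ring = c(8L, 8L, 8L, 1L),
                       ring_angles = c(6, 30, 60, 90),
                       axis_dir = c("inward", "outward")) {
  axis_dir <- match.arg(axis_dir)
  stopifnot_scalar_number(radius, "radius", positive = TRUE)
  if (length(per_ring) != length(ring_angles))
    stop("`per_ring` and `ring_angles` must have the same length")
  if (any(per_ring < 1)) stop("each ring needs at least one sensor")
  if (any(diff(ring_angles) <= 0) || any(ring_angles < 0) || any(ring_angles > 90))
    stop("`ring_angles` must be strictly increasing within [0, 90]")

  pos <- NULL
  ring <- NULL
  for (j in seq_along(ring_angles)) {
    th <- ring_angles[j] * DEG2RAD
    if (ring_angles[j] == 90) {
      # all azimuths coincide at the zenith; place per_ring[j] == 1 sensor
      p <- matrix(c(0, 0, radius), 1L)
      p <- p[rep(1L, per_ring[j]), , drop = FALSE]
    } else {
      az <- 2 * pi * (seq_len(per_ring[j]) - 1L) / per_ring[j]
      p <- cbind(
        radius * cos(th) * cos(az),
        radius * cos(th) * sin(az),
        radius * sin(th)
      )
    }
    pos <- rbind(pos, p)
    ring <- c(ring, rep(ring_angles[j], per_ring[j]))
  }
  phat <- pos / radius
  axes <- if (axis_dir == "inward") -phat else phat
  new_sensor_array(radius, pos, axes, ring, subclass = "pearl_dome")
}

#' Unit position weights of a sensor array
#'
#' Returns the per-sensor unit position vectors p_i / |p_i| used as weights by
#' the orientation reconstruction.
#'
#' @param geom a `sensor_array`.
#' @return an n x 3 matrix of unit rows, in sensor order.
#' @export
position_weights <- function(geom) {
  stopifnot(inherits(geom, "sensor_array"))
  geom$positions / row_norms(geom$positions)
}

#' Dense spherical or hemispherical sensor grid
#'
#' Quasi-uniform (Fibonacci lattice) radial sensor grid on the full sphere or
#' the upper hemisphere, used as a reconstruction oracle: with enough sensors
#' the position-weighted sum of radial readings recovers a central dipole's
#' direction almost exactly.
#'
#' @param n number of sensors.
#' @param radius sphere radius in metres.
#' @param hemisphere if `TRUE`, restrict to z >= 0.
#' @param axis_dir `"outward"` (default) or `"inward"` radial axes.
#' @return a `sensor_array`.
#' @export
sphere_sensor_grid <- function(n, radius = dome_radius_from_volume(4.2),
                               hemisphere = FALSE,
                               axis_dir = c("outward", "inward")) {
  axis_dir <- match.arg(axis_dir)
  stopifnot_scalar_number(radius, "radius", positive = TRUE)
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) 1 - i / n else 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  phat <- cbind(rho * cos(th), rho * sin(th), z)
  axes <- if (axis_dir == "inward") -phat else phat
  new_sensor_array(radius, radius * phat, axes, rep(NA_real_, n))
}

#' Serialize a sensor array to JSON
#'
#' @param geom a `sensor_array`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
geometry_to_json <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "sensor_array"))
  obj <- list(
    radius = geom$radius,
    sensors = lapply(seq_along(geom$index), function(i) {
      list(
        index = geom$index[i],
        position = as.numeric(geom$positions[i, ]),
        axis = as.numeric(geom$axes[i, ]),
        ring = geom$ring[i]
      )
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a sensor array from JSON
#'
#' @param path file or JSON string produced by [geometry_to_json()].
#' @return a `sensor_array`.
#' @export
geometry_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  pos <- do.call(rbind, lapply(obj$sensors, function(s) as.numeric(s$position)))
  axes <- do.call(rbind, lapply(obj$sensors, function(s) as.numeric(s$axis)))
  ring <- vapply(obj$sensors, function(s) as.numeric(s$ring %||% NA_real_), 0)
  new_sensor_array(obj$radius, pos, axes, ring)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array> %d sensors, radius %.4f m%s\n",
    length(x$index), x$radius,
    if (inherits(x, "pearl_dome")) " (hemispherical dome)" else ""
  ))
  rr <- x$ring[!is.na(x$ring)]
  if (length(rr))
    cat("  rings (deg):", paste(unique(rr), collapse = ", "), "\n")
  invisible(x)
}
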