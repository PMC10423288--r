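# Orientation trajectories: timestamped unit-vector series of the magnet
# moment direction, plus their CSV dialect.

#' Construct an orientation trajectory
#'
#' @param t numeric vector of seconds since acquisition start, strictly
#'   increasing.
#' @param u n x 3 matrix of unit rows (magnet moment direction).
#' @param magnet_position length-3 magnet position in dome coordinates
#'   (metres), or `NULL` when unknown (e.g. reconstructed trajectories).
#' @param valid optional logical mask of reliable timestamps.
#' @return an `orientation_trajectory`.
#' @export
orientation_trajectory <- function(t, u, magnet_position = NULL, valid = NULL) {
  u <- as.matrix(u)
  if (ncol(u) != 3L) stop("`u` must have three columns")
  if (length(t) != nrow(u)) stop("`t` and `u` length mismatch")
  if (length(t) > 1L && any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (is.null(valid)) valid <- rep(TRUE, length(t))
  ok <- valid & !is.na(u[, 1L])
  if (any(ok)) {
    n <- row_norms(u[ok, , drop = FALSE])
    if (any(abs(n - 1) > 1e-6)) u[ok, ] <- u[ok, , drop = FALSE] / n
  }
  structure(
    list(t = as.numeric(t), u = u, magnet_position = magnet_position,
         valid = valid),
    class = "orientation_trajectory"
  )
}

traj_dt <- function(traj) {
  if (length(traj$t) < 2L) return(NA_real_)
  stats::median(diff(traj$t))
}

traj_duration <- function(traj) {
  if (!length(traj$t)) return(0)
  traj$t[length(traj$t)] - traj$t[1L]
}

#' @export
print.orientation_trajectory <- function(x, ...) {
  cat(sprintf(
    "<orientation_trajectory> %d samples, %.1f h span, dt = %.3g s, %d flagged\n",
    length(x$t), traj_duration(x) / 3600, traj_dt(x), sum(!x$valid)
  ))
  invisible(x)
}

#' Write / read the trajectory CSV dialect (`t,x,y,z`)
#'
#' @param traj an `orientation_trajectory`.
#' @param path file path.
#' @return `write_trajectory_csv` returns the path invisibly;
#'   `read_trajectory_csv` returns an `orientation_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "orientation_trajectory"))
  df <- data.frame(t = traj$t, x = traj$u[, 1L], y = traj$u[, 2L],
                   z = traj$u[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  orientation_trajectory(df$t, as.matrix(df[, c("x", "y", "z")]))
}

# Subset a trajectory by index, keeping metadata.
traj_slice <- function(traj, idx) {
  orientation_trajectory(
    traj$t[idx], traj$u[idx, , drop = FALSE],
    magnet_position = traj$magnet_position,
    valid = traj$valid[idx]
  )
}
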