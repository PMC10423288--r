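# Internal geometry and RNG helpers shared across the package.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- NA_real_
  m / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Rotate a 3-vector about an axis
#'
#' Rodrigues rotation of `v` by `angle_deg` degrees about the unit vector
#' `axis` (right-hand rule).
#'
#' @param v numeric length-3 vector.
#' @param axis unit length-3 rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return the rotated length-3 vector.
#' @keywords internal
rotate_vec <- function(v, axis, angle_deg) {
  ang <- angle_deg * DEG2RAD
  ca <- cos(ang)
  sa <- sin(ang)
  v * ca + cross3(axis, v) * sa + axis * sum(axis * v) * (1 - ca)
}

# Rotate every row of U (n x 3) about a single fixed axis by per-row angles.
rotate_rows <- function(U, axis, angles_deg) {
  ang <- angles_deg * DEG2RAD
  ca <- cos(ang)
  sa <- sin(ang)
  K <- rbind(
    c(0, -axis[3L], axis[2L]),
    c(axis[3L], 0, -axis[1L]),
    c(-axis[2L], axis[1L], 0)
  )
  KU <- U %*% t(K)
  proj <- drop(U %*% axis)
  U * ca + KU * sa + outer(proj * (1 - ca), axis)
}

# Angle in degrees between rows of two n x 3 unit matrices (or one matrix and
# a single vector).
angle_between <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow(a), 3L, byrow = TRUE)
  acos(clamp(rowSums(a * b), -1, 1)) * RAD2DEG
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_unit <- function() normalize(stats::rnorm(3L))

# A unit vector orthogonal to u, uniformly distributed in the tangent plane.
random_tangent <- function(u) {
  repeat {
    a <- stats::rnorm(3L)
    a <- a - sum(a * u) * u
    n <- vec_norm(a)
    if (n > 1e-9) return(a / n)
  }
}

wrap360 <- function(x) x %% 360

# Wrap angle differences into (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Derive a stream of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite number", name))
  if (positive && x <= 0) stop(sprintf("`%s` must be positive", name))
  invisible(x)
}
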