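# Shared fixtures, built in code at test time.

# A static trajectory pointing along `u` for `n` samples at `rate` Hz.
static_traj <- function(u = c(0, 0, 1), n = 10L, rate = 1,
                        magnet_position = default_magnet_position()) {
  orientation_trajectory(
    (seq_len(n) - 1L) / rate,
    matrix(u / sqrt(sum(u^2)), n, 3L, byrow = TRUE),
    magnet_position = magnet_position
  )
}

# Steady rotation of u0 about `axis` at `speed` deg/min.
rotation_traj <- function(duration = 3600, rate = 1, speed = 6,
                          axis = c(0, 0, 1), u0 = c(1, 0, 0),
                          magnet_position = default_magnet_position()) {
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  U <- pearlrot:::rotate_rows(matrix(u0, n, 3L, byrow = TRUE), axis,
                              speed / 60 * t)
  orientation_trajectory(t, U, magnet_position = magnet_position)
}

# Small render spec used by imaging unit tests (full 224 only where the
# classifier needs it).
small_spec <- function(...) render_spec(size = 64L, point_px = 1L, ...)

# Linearly separable 3-class feature set for classifier capacity tests.
separable_samples <- function(n_per_class = 8L, d = 6L, seed = 1L,
                              gap = 6) {
  classes <- pearl_classes()
  pearlrot:::with_seed(seed, {
    feats <- NULL
    labels <- character(0)
    ids <- character(0)
    for (i in seq_along(classes)) {
      centre <- rep(0, d)
      centre[i] <- gap
      feats <- rbind(feats, matrix(stats::rnorm(n_per_class * d), ncol = d) +
                       matrix(centre, n_per_class, d, byrow = TRUE))
      labels <- c(labels, rep(classes[i], n_per_class))
      ids <- c(ids, sprintf("%s%02d", substr(classes[i], 1, 1),
                            seq_len(n_per_class)))
    }
    list(features = feats, labels = labels, pearl_id = ids,
         culture_days = rep(200, length(labels)),
         acq_offset_days = rep(50, length(labels)))
  })
}

# Area under the ROC curve of score vs binary truth (rank statistic).
simple_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
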