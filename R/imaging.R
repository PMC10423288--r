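# Trajectory-to-image rendering: weekly/daily segmentation, barycenter
# viewpoint, deterministic software rasterization of sphere-projected
# rotation data, and dataset assembly (day / week / month / full variants).

#' Rendering specification
#'
#' Frozen rendering style so images are bit-reproducible across runs and
#' platforms: dark background, trajectory points coloured by time order with
#' a perceptually uniform colormap, optional sphere outline, no axes.
#'
#' @param size image side in pixels (square).
#' @param n_views number of rotated views per segment.
#' @param view_step in-plane rotation between consecutive views (degrees).
#' @param point_px point size in pixels.
#' @param palette a `grDevices::hcl.colors` palette name.
#' @param background RGB background triplet (0-255).
#' @param wireframe draw the sphere outline circle.
#' @return a `render_spec`.
#' @export
render_spec <- function(size = 224L, n_views = 6L, view_step = 60,
                        point_px = 2L, palette = "viridis",
                        background = c(10L, 10L, 14L), wireframe = TRUE) {
  if (size <= 0) stop("`size` must be positive")
  if (n_views * view_step > 360) stop("`n_views * view_step` must be <= 360")
  structure(
    list(size = as.integer(size), n_views = as.integer(n_views),
         view_step = view_step, point_px = as.integer(point_px),
         palette = palette, background = as.integer(background),
         wireframe = isTRUE(wireframe)),
    class = "render_spec"
  )
}

#' Segment a trajectory into days or weeks
#'
#' Cuts a trajectory into contiguous non-overlapping segments of 86,400 s
#' (day) or 604,800 s (week) from its start. A trailing partial segment is
#' kept only if it covers at least half the segment length.
#'
#' @param traj an [orientation_trajectory()].
#' @param granularity `"week"` or `"day"`.
#' @return list of [orientation_trajectory()]s, each with attribute
#'   `period_start_s` (seconds from the trajectory start).
#' @export
segment_trajectory <- function(traj, granularity = c("week", "day")) {
  stopifnot(inherits(traj, "orientation_trajectory"))
  granularity <- match.arg(granularity)
  if (!length(traj$t)) stop("empty trajectory")
  seg_len <- if (granularity == "week") 604800 else 86400
  rel <- traj$t - traj$t[1L]
  seg_id <- floor(rel / seg_len)
  segs <- list()
  for (k in sort(unique(seg_id))) {
    idx <- which(seg_id == k)
    covered <- rel[idx[length(idx)]] - k * seg_len
    full <- any(seg_id > k) # a later segment exists => this one is complete
    if (!full && covered < 0.5 * seg_len) next
    s <- traj_slice(traj, idx)
    attr(s, "period_start_s") <- k * seg_len
    attr(s, "shape_class") <- attr(traj, "shape_class")
    segs[[length(segs) + 1L]] <- s
  }
  segs
}

#' Barycenter viewpoint of a trajectory segment
#'
#' Camera direction maximizing the visible rotation data: the normalized mean
#' of the segment's unit vectors. When the mean is degenerate (antipodally
#' balanced data, e.g. a full great circle), falls back to the least-variance
#' principal axis of the point cloud — the normal of the plane the data lies
#' in — with the sign fixed into the upper hemisphere.
#'
#' @param segment an [orientation_trajectory()].
#' @return unit length-3 camera direction.
#' @export
barycenter_viewpoint <- function(segment) {
  stopifnot(inherits(segment, "orientation_trajectory"))
  U <- segment$u[segment$valid & !is.na(segment$u[, 1L]), , drop = FALSE]
  if (!nrow(U)) stop("no valid points in segment")
  m <- colMeans(U)
  n <- vec_norm(m)
  if (n >= 1e-6) return(m / n)
  sc <- crossprod(U) / nrow(U)
  e <- eigen(sc, symmetric = TRUE)
  v <- e$vectors[, 3L] # least-variance axis = normal of the data plane
  # deterministic sign: first of (z, x, y) with |.| > tol points positive
  for (j in c(3L, 1L, 2L)) {
    if (abs(v[j]) > 1e-9) {
      if (v[j] < 0) v <- -v
      break
    }
  }
  v
}

# Orthonormal in-plane basis (right, up) for a camera direction, rolled by
# `roll_deg` about the camera axis. Basis convention: right = z x cam
# (horizontal) unless cam is near-vertical, in which case right = +x.
camera_basis <- function(cam, roll_deg = 0) {
  if (abs(cam[3L]) < 0.999) {
    e1 <- normalize(cross3(c(0, 0, 1), cam))
  } else {
    e1 <- c(1, 0, 0)
    e1 <- normalize(e1 - sum(e1 * cam) * cam)
  }
  e2 <- cross3(cam, e1)
  if (roll_deg != 0) {
    e1 <- rotate_vec(e1, cam, roll_deg)
    e2 <- rotate_vec(e2, cam, roll_deg)
  }
  list(e1 = e1, e2 = e2)
}

render_palette <- function(spec, n = 256L) {
  cols <- grDevices::hcl.colors(n, spec$palette)
  t(grDevices::col2rgb(cols)) # n x 3, 0-255
}

blank_canvas <- function(spec) {
  size <- spec$size
  img <- array(0L, dim = c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- spec$background[ch]
  if (spec$wireframe) {
    ctr <- (size + 1) / 2
    rad <- size / 2 - 1
    ij <- expand.grid(i = seq_len(size), j = seq_len(size))
    d <- sqrt((ij$i - ctr)^2 + (ij$j - ctr)^2)
    ring <- which(d <= rad & d >= rad - 1.5)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ring] <- c(60L, 60L, 70L)[ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Render one orthographic view of a trajectory segment
#'
#' Projects the segment's unit vectors orthographically along `camera`
#' (front-facing points only), rasterizes them in time order (later points
#' drawn on top) with a time-ordered colormap, on the canvas defined by
#' `spec`. Fully deterministic.
#'
#' @param segment an [orientation_trajectory()].
#' @param spec a [render_spec()].
#' @param camera unit camera direction; defaults to
#'   [barycenter_viewpoint()].
#' @param roll_deg in-plane rotation of the view basis (degrees).
#' @return `size x size x 3` integer array, RGB 0-255.
#' @export
render_view <- function(segment, spec = render_spec(), camera = NULL,
                        roll_deg = 0) {
  stopifnot(inherits(segment, "orientation_trajectory"),
            inherits(spec, "render_spec"))
  img <- blank_canvas(spec)
  keep <- which(segment$valid & !is.na(segment$u[, 1L]))
  if (!length(keep)) return(img)
  camera <- camera %||% barycenter_viewpoint(segment)
  basis <- camera_basis(camera, roll_deg)
  U <- segment$u[keep, , drop = FALSE]
  front <- drop(U %*% camera) >= 0
  if (!any(front)) return(img)
  U <- U[front, , drop = FALSE]
  ord <- order(segment$t[keep][front]) # draw in time order
  U <- U[ord, , drop = FALSE]

  size <- spec$size
  a <- drop(U %*% basis$e1)
  b <- drop(U %*% basis$e2)
  col <- clamp(floor((a + 1) / 2 * size) + 1L, 1L, size)
  row <- clamp(floor((1 - b) / 2 * size) + 1L, 1L, size)

  npts <- nrow(U)
  shade <- if (npts > 1L)
    1L + floor((seq_len(npts) - 1L) / (npts - 1L) * 255L)
  else rep(256L, 1L)
  pal <- render_palette(spec)

  pp <- spec$point_px
  offs <- expand.grid(dr = 0:(pp - 1L), dc = 0:(pp - 1L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    for (k in seq_len(nrow(offs))) {
      r <- pmin(size, row + offs$dr[k])
      cc <- pmin(size, col + offs$dc[k])
      plane[cbind(r, cc)] <- pal[shade, ch]
    }
    img[, , ch] <- plane
  }
  img
}

#' Render the rotated view set of a segment
#'
#' View 0 looks along the barycenter viewpoint; each subsequent view rotates
#' the scene by `view_step` degrees about the camera axis (views are in-plane
#' rotations of the same projection, as acquired by the monitoring software).
#'
#' @param segment an [orientation_trajectory()].
#' @param spec a [render_spec()].
#' @return list of `n_views` image arrays; view 0 is element 1.
#' @export
render_views <- function(segment, spec = render_spec()) {
  camera <- barycenter_viewpoint(segment)
  lapply(seq_len(spec$n_views) - 1L, function(k)
    render_view(segment, spec, camera = camera,
                roll_deg = -k * spec$view_step))
}

#' Write an image array as PNG
#'
#' @param img `h x w x 3` array, RGB 0-255.
#' @param path output file.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Fraction of non-background pixels
#'
#' Simple occupancy statistic of a rendered image; useful as a rendering
#' sanity check (near-static pearls occupy almost no pixels).
#'
#' @param img image array from [render_view()].
#' @param spec the [render_spec()] used (for background and wireframe).
#' @return fraction in \[0, 1\].
#' @export
image_occupancy <- function(img, spec = render_spec()) {
  blank <- blank_canvas(spec)
  mean(img[, , 1L] != blank[, , 1L] | img[, , 2L] != blank[, , 2L] |
         img[, , 3L] != blank[, , 3L])
}

new_pearl_sample <- function(image, pearl_id, label, culture_days,
                             acq_offset_days, period) {
  structure(
    list(image = image, pearl_id = pearl_id, label = label,
         culture_days = culture_days, acq_offset_days = acq_offset_days,
         period = period),
    class = "pearl_sample"
  )
}

#' Assemble an image dataset from a cohort
#'
#' Segments each pearl's trajectory into weeks, renders the first (view 0)
#' image per segment, and assembles one of the four dataset variants:
#' \describe{
#'   \item{full}{every weekly segment of every pearl.}
#'   \item{week}{the last weekly segment per pearl (one sample per pearl).}
#'   \item{month}{the last up-to-four weekly segments per pearl.}
#'   \item{day}{the last weekly segment split into daily segments (up to
#'     seven samples per pearl).}
#' }
#' Each sample carries the pearl's cultivation days and the days from graft
#' to its own segment start.
#'
#' @param cohort a `pearl_cohort`.
#' @param variant `"full"`, `"week"`, `"month"` or `"day"`.
#' @param spec a [render_spec()].
#' @param trajectories optional named list (by pearl_id) of trajectories to
#'   use instead of each record's own (e.g. reconstructed ones).
#' @return a `pearl_dataset`: list with `samples` and `variant`.
#' @export
assemble_dataset <- function(cohort, variant = c("full", "week", "month", "day"),
                             spec = render_spec(), trajectories = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(cohort, "pearl_cohort"))
  if (!length(cohort)) stop("empty cohort")
  samples <- list()
  for (rec in cohort) {
    traj <- trajectories[[rec$pearl_id]] %||% rec$trajectory
    weeks <- segment_trajectory(traj, "week")
    if (!length(weeks)) next
    segs <- switch(variant,
      full = weeks,
      week = weeks[length(weeks)],
      month = weeks[seq(max(1L, length(weeks) - 3L), length(weeks))],
      day = segment_trajectory(weeks[[length(weeks)]], "day")
    )
    if (variant == "day") {
      base_off <- attr(weeks[[length(weeks)]], "period_start_s")
      segs <- lapply(segs, function(s) {
        attr(s, "period_start_s") <- base_off + attr(s, "period_start_s")
        s
      })
    }
    for (s in segs) {
      start_day <- rec$acq_offset_days + attr(s, "period_start_s") / 86400
      end_day <- start_day + traj_duration(s) / 86400
      img <- render_view(s, spec)
      samples[[length(samples) + 1L]] <- new_pearl_sample(
        img, rec$pearl_id, rec$true_class, rec$culture_days,
        start_day, c(start_day, end_day)
      )
    }
  }
  structure(list(samples = samples, variant = variant, spec = spec),
            class = "pearl_dataset")
}

#' @export
print.pearl_dataset <- function(x, ...) {
  cat(sprintf("<pearl_dataset> variant '%s': %d samples from %d pearls\n",
              x$variant, length(x$samples),
              length(unique(vapply(x$samples, `[[`, "", "pearl_id")))))
  invisible(x)
}

#' Dataset manifest as a data frame
#'
#' @param dataset a `pearl_dataset`.
#' @param image_paths optional character vector of stored image paths.
#' @return data frame with one row per sample.
#' @export
dataset_manifest <- function(dataset, image_paths = NA_character_) {
  stopifnot(inherits(dataset, "pearl_dataset"))
  do.call(rbind, lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    data.frame(
      pearl_id = s$pearl_id, label = s$label, variant = dataset$variant,
      period_start_day = s$period[1L], period_end_day = s$period[2L],
      culture_days = s$culture_days, acq_offset_days = s$acq_offset_days,
      image_path = if (length(image_paths) >= i) image_paths[i] else NA
    )
  }))
}
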