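# Configuration-driven experiment drivers tying the stages together:
# simulate -> smooth -> reconstruct -> render -> assemble -> evaluate.

#' Build an experiment configuration
#'
#' Nested configuration with explicit seeds for every random stage; round
#' trips losslessly through YAML. Any subset of fields can be overridden.
#'
#' @param ... named overrides of the defaults, nested lists merged
#'   recursively (e.g. `simulation = list(n_pearls = 12)`).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(...) {
  defaults <- list(
    geometry = list(volume_l = 4.2, per_ring = c(8L, 8L, 8L, 1L),
                    ring_angles = c(6, 30, 60, 90)),
    simulation = list(
      n_pearls = 60L,
      class_probs = list(Round = 0.276, Atypical = 0.213, Other = 0.511),
      speed_mean = 0.69, speed_sd = 0.13,
      culture_day_range = c(180L, 365L),
      acquisition_days = 21, rate = 1 / 60,
      noise_frac = 0.05, offset_frac = 0.01, seed = 1L
    ),
    pipeline = list(window = 60L, pole_cut = 0.95, floor_frac = 0.01,
                    smooth = TRUE, speed_lag_s = 120),
    imaging = list(size = 224L, n_views = 6L, view_step = 60, point_px = 2L,
                   palette = "viridis", wireframe = TRUE),
    model = list(backbone = "tiny-cnn", dense_widths = 256L,
                 dropout_rates = 0.5, lr = 1e-3, epochs = 30L, batch = 16L),
    evaluation = list(n_repeats = 10L,
                      fractions = c(train = 0.70, val = 0.15, test = 0.15),
                      variants = c("full", "week", "day"), seed = 1L)
  )
  over <- list(...)
  cfg <- utils::modifyList(defaults, over)
  # normalize containers so YAML round trips compare equal
  cfg$evaluation$fractions <- unlist(cfg$evaluation$fractions)
  cfg$geometry$per_ring <- as.integer(unlist(cfg$geometry$per_ring))
  cfg$geometry$ring_angles <- as.numeric(unlist(cfg$geometry$ring_angles))
  cfg$simulation$culture_day_range <-
    as.integer(unlist(cfg$simulation$culture_day_range))
  cfg$simulation$class_probs <- as.list(cfg$simulation$class_probs)
  stopifnot(cfg$simulation$n_pearls >= 0, cfg$evaluation$n_repeats >= 1)
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  obj <- unclass(config)
  # named atomic vectors serialize as sequences (names lost); use a map
  obj$evaluation$fractions <- as.list(obj$evaluation$fractions)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialization, recorded in every output
#' manifest so artifacts are traceable to the exact configuration.
#'
#' @param config an `experiment_config`.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config_yaml(config, tf)
  unname(tools::md5sum(tf))
}

config_geometry <- function(config) {
  build_dome(radius = dome_radius_from_volume(config$geometry$volume_l),
             per_ring = config$geometry$per_ring,
             ring_angles = config$geometry$ring_angles)
}

config_render_spec <- function(config) {
  im <- config$imaging
  render_spec(size = im$size, n_views = im$n_views, view_step = im$view_step,
              point_px = im$point_px, palette = im$palette,
              wireframe = im$wireframe)
}

config_cohort <- function(config) {
  sm <- config$simulation
  simulate_cohort(
    n_pearls = sm$n_pearls, class_probs = unlist(sm$class_probs),
    speed_mean = sm$speed_mean, speed_sd = sm$speed_sd,
    culture_day_range = sm$culture_day_range,
    acquisition_days = sm$acquisition_days, rate = sm$rate, seed = sm$seed
  )
}

log_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- force(expr)
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("[pearlrot] %-12s %.1fs", name, dt))
  res
}

#' Simulate a cohort and write its raw artifacts
#'
#' Generates the configured cohort, writes per-pearl trajectory and
#' 25-channel recording CSVs plus a manifest JSON carrying the config hash,
#' seeds, metadata and per-file MD5 checksums.
#'
#' @param config an `experiment_config`.
#' @param outdir writable output directory.
#' @return the manifest (invisibly).
#' @export
run_simulate <- function(config = experiment_config(), outdir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory")
  geom <- config_geometry(config)
  cohort <- log_stage("simulate", config_cohort(config))
  files <- character(0)
  for (rec in cohort) {
    tp <- file.path(outdir, paste0(rec$pearl_id, "_trajectory.csv"))
    rp <- file.path(outdir, paste0(rec$pearl_id, "_recording.csv"))
    write_trajectory_csv(rec$trajectory, tp)
    sr <- simulate_recording(
      rec$trajectory, geom,
      noise_frac = config$simulation$noise_frac,
      offset_frac = config$simulation$offset_frac,
      seed = config$simulation$seed + match(rec$pearl_id,
                                            vapply(cohort, `[[`, "", "pearl_id"))
    )
    write_recording_csv(sr, rp)
    files <- c(files, tp, rp)
  }
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$simulation$seed,
    n_pearls = length(cohort),
    pearls = if (length(cohort)) cohort_metadata(cohort) else list(),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(outdir, "manifest.json"))
  message(sprintf("[pearlrot] wrote %d files for %d pearls to %s",
                  length(files), length(cohort), outdir))
  invisible(manifest)
}

#' Reconstruct every pearl's trajectory from its simulated recording
#'
#' The measurement path of the full experiment: forward-simulate each
#' pearl's 25-channel recording, Gaussian-smooth it, and reconstruct the
#' orientation trajectory used for rendering.
#'
#' @param cohort a `pearl_cohort`.
#' @param config an `experiment_config`.
#' @param geom dome geometry (defaults to the configured one).
#' @return named list of reconstructed [orientation_trajectory()]s.
#' @export
reconstruct_cohort <- function(cohort, config = experiment_config(),
                               geom = NULL) {
  geom <- geom %||% config_geometry(config)
  sm <- config$simulation
  pl <- config$pipeline
  out <- list()
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    sr <- simulate_recording(rec$trajectory, geom,
                             noise_frac = sm$noise_frac,
                             offset_frac = sm$offset_frac,
                             seed = sm$seed + i)
    if (isTRUE(pl$smooth) && length(sr$t) >= pl$window)
      sr <- gaussian_smooth(sr, window = pl$window)
    out[[rec$pearl_id]] <- reconstruct_orientation(sr, geom,
                                                   floor_frac = pl$floor_frac)
  }
  out
}

#' Run the full experiment: simulate, reconstruct, render, evaluate
#'
#' Executes the complete pipeline for each configured dataset variant and
#' evaluates with grouped repeated holdout. Writes (when `outdir` is given)
#' the per-repeat metrics CSV per variant and a human-readable report of
#' per-variant accuracy and F1.
#'
#' @param config an `experiment_config`.
#' @param outdir optional output directory.
#' @return list with `metrics` (named by variant, `metrics_summary`),
#'   `report` (data frame), `config_hash`.
#' @export
run_full_experiment <- function(config = experiment_config(), outdir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  geom <- config_geometry(config)
  cohort <- log_stage("simulate", config_cohort(config))
  if (!length(cohort)) stop("empty cohort; increase simulation$n_pearls")
  recon <- log_stage("reconstruct", reconstruct_cohort(cohort, config, geom))
  spec <- config_render_spec(config)
  backbone <- backbone_spec(config$model$backbone)
  head <- head_spec(config$model$dense_widths, config$model$dropout_rates)
  hyper <- config$model[c("lr", "epochs", "batch")]
  md <- cohort_metadata(cohort)
  pearl_tab <- data.frame(pearl_id = md$pearl_id, label = md$true_class,
                          harvest_date_group = md$harvest_date_group)

  metrics <- list()
  for (v in config$evaluation$variants) {
    ds <- log_stage(paste0("render:", v),
                    assemble_dataset(cohort, v, spec, trajectories = recon))
    metrics[[v]] <- log_stage(paste0("evaluate:", v), repeated_holdout(
      ds, n_repeats = config$evaluation$n_repeats, head = head,
      hyper = hyper, backbone = backbone,
      fractions = config$evaluation$fractions,
      seed = config$evaluation$seed, pearls = pearl_tab))
  }

  report <- do.call(rbind, lapply(names(metrics), function(v) {
    ag <- metrics[[v]]$aggregate
    data.frame(
      variant = v, level = ag$level,
      accuracy = ag$accuracy_mean, accuracy_sd = ag$accuracy_sd,
      weighted_f1 = ag$weighted_f1_mean, macro_f1 = ag$macro_f1_mean,
      f1_other = ag$f1_other_mean, f1_atypical = ag$f1_atypical_mean,
      f1_round = ag$f1_round_mean
    )
  }))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (v in names(metrics))
      write_metrics_csv(metrics[[v]],
                        file.path(outdir, paste0("metrics_", v, ".csv")))
    utils::write.csv(report, file.path(outdir, "report.csv"),
                     row.names = FALSE)
    con <- file(file.path(outdir, "report.txt"), "w")
    writeLines(c(
      sprintf("pearlrot experiment report (config %s)", config_hash(config)),
      sprintf("%d pearls, variants: %s", length(cohort),
              paste(names(metrics), collapse = ", ")),
      utils::capture.output(print(report, row.names = FALSE, digits = 3))
    ), con)
    close(con)
  }
  list(metrics = metrics, report = report, config_hash = config_hash(config))
}
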