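# Grouped, stratified repeated-holdout evaluation, classification metrics,
# hyperparameter grid search, and the graft-survival summary table.

#' Grouped stratified train/val/test split
#'
#' Randomizes *pearls* (never individual samples) into train / validation /
#' test splits. Within each shape class, pearls are apportioned to splits by
#' largest-remainder rounding so per-split class counts stay within one pearl
#' of the global proportions; within a class, pearls are ordered by harvest
#' date group (shuffled within group) and split labels are interleaved evenly
#' so each harvest group is represented in every split where its size
#' permits. Deterministic per seed.
#'
#' @param pearls a data frame with columns `pearl_id`, `label` and optionally
#'   `harvest_date_group`; or a `pearl_cohort`; or a `pearl_dataset` (unique
#'   pearls are taken from its samples).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed.
#' @return a `split_plan` data frame (`pearl_id`, `label`, `split`) with
#'   attributes `fractions` and `seed`.
#' @export
grouped_stratified_split <- function(pearls,
                                     fractions = c(train = 0.70, val = 0.15,
                                                   test = 0.15),
                                     seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1")
  if (inherits(pearls, "pearl_cohort")) {
    md <- cohort_metadata(pearls)
    pearls <- data.frame(pearl_id = md$pearl_id, label = md$true_class,
                         harvest_date_group = md$harvest_date_group)
  } else if (inherits(pearls, "pearl_dataset")) {
    ids <- vapply(pearls$samples, `[[`, "", "pearl_id")
    labs <- vapply(pearls$samples, `[[`, "", "label")
    keep <- !duplicated(ids)
    pearls <- data.frame(pearl_id = ids[keep], label = labs[keep])
  }
  if (is.null(pearls$harvest_date_group))
    pearls$harvest_date_group <- "all"
  splits <- c("train", "val", "test")

  assign_split <- with_seed(seed, {
    out <- character(nrow(pearls))
    for (cl in unique(pearls$label)) {
      rows <- which(pearls$label == cl)
      counts <- apportion(length(rows), fractions)
      # order pearls by harvest group, shuffled within group
      grp <- pearls$harvest_date_group[rows]
      ord <- order(grp, stats::runif(length(rows)))
      rows <- rows[ord]
      # interleave split labels evenly: each split's k-th member sits at
      # fractional rank (k - u_s) / n_s, then merge-sort by rank
      lab <- character(0)
      rank <- numeric(0)
      for (s in seq_along(splits)) {
        if (counts[s] == 0L) next
        u <- stats::runif(1L)
        lab <- c(lab, rep(splits[s], counts[s]))
        rank <- c(rank, (seq_len(counts[s]) - u) / counts[s])
      }
      out[rows] <- lab[order(rank)]
    }
    out
  })
  plan <- data.frame(pearl_id = pearls$pearl_id, label = pearls$label,
                     split = assign_split)
  attr(plan, "fractions") <- fractions
  attr(plan, "seed") <- seed
  class(plan) <- c("split_plan", "data.frame")
  plan
}

# Largest-remainder apportionment of n items into length(fractions) bins.
# Ties go to earlier bins (train before val before test).
apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, -seq_along(fractions), decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Serialize a split plan to JSON
#'
#' @param plan a `split_plan`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @export
split_plan_to_json <- function(plan, path = NULL) {
  obj <- list(fractions = as.list(attr(plan, "fractions")),
              seed = attr(plan, "seed"),
              assignment = stats::setNames(as.list(plan$split), plan$pearl_id))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Multiclass classification metrics
#'
#' Accuracy, per-class F1 (harmonic mean of precision and recall, defined as
#' 0 when undefined), macro-average F1 (unweighted mean of the per-class
#' F1s) and weighted-average F1 (weighted by true-class support).
#'
#' @param true,pred character vectors of true and predicted labels.
#' @param classes class set and order; defaults to [pearl_classes()].
#' @return one-row data frame: `accuracy`, `weighted_f1`, `macro_f1`, then
#'   one `f1_<class>` column per class.
#' @export
classification_metrics <- function(true, pred, classes = pearl_classes()) {
  if (!length(true) || length(true) != length(pred))
    stop("`true` and `pred` must be equal-length, nonempty")
  true <- factor(true, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(true, pred)
  f1 <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  support <- rowSums(cm)
  out <- data.frame(
    accuracy = sum(diag(cm)) / sum(cm),
    weighted_f1 = sum(f1 * support) / sum(support),
    macro_f1 = mean(f1)
  )
  for (i in seq_along(classes))
    out[[paste0("f1_", tolower(classes[i]))]] <- f1[i]
  out
}

#' Repeated-holdout evaluation of the shape classifier
#'
#' For each repeat: draw a fresh grouped stratified split, train the head on
#' the train split (early-stopped on the validation split), and evaluate on
#' the test split at the sample level and at the pearl level (majority vote
#' over each pearl's samples). Repeats are independent, with seeds derived
#' from the master seed. Repeats whose test split misses a class are flagged
#' and excluded from per-class aggregation.
#'
#' @param dataset a `pearl_dataset`.
#' @param n_repeats number of holdout repeats.
#' @param head a [head_spec()].
#' @param hyper hyperparameter list, see [train_classifier()].
#' @param backbone a [backbone_spec()].
#' @param fractions train/val/test fractions.
#' @param seed master seed.
#' @param pearls optional pearl table (with harvest groups) for the split;
#'   defaults to the pearls present in the dataset.
#' @param features optional pre-extracted feature matrix for the dataset.
#' @return a `metrics_summary`: list with `per_repeat` (one row per repeat
#'   and level) and `aggregate` (mean and sd per metric and level).
#' @export
repeated_holdout <- function(dataset, n_repeats = 100L, head = head_spec(),
                             hyper = list(), backbone = backbone_spec("tiny-cnn"),
                             fractions = c(train = 0.70, val = 0.15, test = 0.15),
                             seed = 1L, pearls = NULL, features = NULL) {
  stopifnot(inherits(dataset, "pearl_dataset"))
  if (is.null(features)) features <- extract_features_dataset(dataset, backbone)
  d <- prepare_samples(dataset, backbone, features = features)
  if (is.null(pearls)) {
    keep <- !duplicated(d$pearl_id)
    pearls <- data.frame(pearl_id = d$pearl_id[keep], label = d$labels[keep])
  }
  seeds <- derive_seeds(seed, 2L * n_repeats)
  split_seeds <- seeds[seq_len(n_repeats)]
  train_seeds <- seeds[n_repeats + seq_len(n_repeats)]

  subset_samples <- function(idx) {
    list(features = d$features[idx, , drop = FALSE],
         culture_days = d$culture_days[idx],
         acq_offset_days = d$acq_offset_days[idx],
         labels = d$labels[idx], pearl_id = d$pearl_id[idx])
  }

  na_metrics <- function(r, level) {
    row <- classification_metrics(pearl_classes(), pearl_classes())
    row[1L, ] <- NA_real_
    cbind(data.frame(repeat_index = r, level = level, degenerate = TRUE), row)
  }

  rows <- list()
  for (r in seq_len(n_repeats)) {
    plan <- grouped_stratified_split(pearls, fractions, seed = split_seeds[r])
    side <- stats::setNames(plan$split, plan$pearl_id)[d$pearl_id]
    if (!all(c("train", "val", "test") %in% side)) {
      # a split came out empty (tiny cohort): record a flagged empty repeat
      rows[[length(rows) + 1L]] <- na_metrics(r, "sample")
      rows[[length(rows) + 1L]] <- na_metrics(r, "pearl")
      next
    }
    hy <- utils::modifyList(hyper, list(seed = train_seeds[r]))
    model <- suppressWarnings(train_classifier(
      subset_samples(which(side == "train")),
      subset_samples(which(side == "val")),
      head = head, hyper = hy, backbone = backbone))
    te <- which(side == "test")
    pr <- predict_dataset(model, subset_samples(te))
    degenerate <- !all(pearl_classes() %in% pr$label)

    sample_m <- classification_metrics(pr$label, pr$pred)
    ids <- unique(pr$pearl_id)
    pearl_true <- vapply(ids, function(id)
      pr$label[match(id, pr$pearl_id)], "")
    pearl_pred <- vapply(ids, function(id)
      vote_pearl(pr$probs[pr$pearl_id == id, , drop = FALSE],
                 model$classes), "")
    pearl_m <- classification_metrics(pearl_true, pearl_pred)

    rows[[length(rows) + 1L]] <- cbind(
      data.frame(repeat_index = r, level = "sample", degenerate = degenerate),
      sample_m)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(repeat_index = r, level = "pearl", degenerate = degenerate),
      pearl_m)
  }
  per_repeat <- do.call(rbind, rows)
  metrics_summary(per_repeat)
}

#' Aggregate per-repeat metrics into a summary
#'
#' @param per_repeat data frame as produced by [repeated_holdout()].
#' @return a `metrics_summary` with `per_repeat` and `aggregate` (mean and sd
#'   per metric and level; per-class F1 columns aggregate over non-degenerate
#'   repeats only).
#' @export
metrics_summary <- function(per_repeat) {
  metric_cols <- setdiff(names(per_repeat),
                         c("repeat_index", "level", "degenerate"))
  agg <- do.call(rbind, lapply(unique(per_repeat$level), function(lv) {
    sub <- per_repeat[per_repeat$level == lv, ]
    row <- data.frame(level = lv, n_repeats = nrow(sub))
    for (mc in metric_cols) {
      vals <- if (startsWith(mc, "f1_") && any(!sub$degenerate))
        sub[[mc]][!sub$degenerate] else sub[[mc]]
      vals <- vals[!is.na(vals)]
      row[[paste0(mc, "_mean")]] <- mean(vals)
      row[[paste0(mc, "_sd")]] <- if (length(vals) > 1L) stats::sd(vals) else 0
    }
    row
  }))
  structure(list(per_repeat = per_repeat, aggregate = agg),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("<metrics_summary>\n")
  print(x$aggregate, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write the per-repeat metrics CSV
#'
#' Columns: `repeat,level,accuracy,weighted_f1,macro_f1,f1_other,
#' f1_atypical,f1_round`.
#'
#' @param summary a `metrics_summary`.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(summary, path) {
  stopifnot(inherits(summary, "metrics_summary"))
  df <- summary$per_repeat
  names(df)[names(df) == "repeat_index"] <- "repeat"
  utils::write.csv(
    df[, c("repeat", "level", "accuracy", "weighted_f1", "macro_f1",
           "f1_other", "f1_atypical", "f1_round")],
    path, row.names = FALSE)
  invisible(path)
}

#' Hyperparameter grid search
#'
#' Exhaustively trains one model per grid row on the train split and selects
#' the configuration with the highest validation accuracy; ties are broken
#' by fewer epochs, then lower learning rate, then grid order.
#'
#' @param train,val as in [train_classifier()].
#' @param grid a data frame of hyperparameter combinations (columns among
#'   `lr`, `epochs`, `batch`) or a list of hyperparameter lists.
#' @param head a [head_spec()].
#' @param backbone a [backbone_spec()].
#' @param seed training seed shared by all configurations.
#' @return list with `best` (hyperparameter list), `results` (data frame
#'   with `val_acc` per configuration).
#' @export
grid_search <- function(train, val, grid, head = head_spec(),
                        backbone = backbone_spec("tiny-cnn"), seed = 1L) {
  if (is.data.frame(grid)) {
    if (!nrow(grid)) stop("empty grid")
    grid <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  }
  if (!length(grid)) stop("empty grid")
  results <- do.call(rbind, lapply(seq_along(grid), function(i) {
    hy <- utils::modifyList(grid[[i]], list(seed = seed))
    model <- suppressWarnings(
      train_classifier(train, val, head = head, hyper = hy,
                       backbone = backbone))
    data.frame(config = i,
               lr = model$hyper$lr, epochs = model$hyper$epochs,
               batch = model$hyper$batch,
               val_acc = max(model$history$val_acc))
  }))
  ord <- order(-results$val_acc, results$epochs, results$lr, results$config)
  best_i <- results$config[ord[1L]]
  list(best = grid[[best_i]], results = results)
}

#' Graft-survival summary table
#'
#' Percent of oysters still carrying their nucleus one month after grafting,
#' per nucleus-quality group, with a totals row. Percentages are truncated
#' to whole numbers, matching the convention of the published table.
#'
#' @param counts data frame with columns `label`, `n_grafted`,
#'   `n_remaining` (and optionally `experiment`).
#' @return a `survival_summary` data frame with `percent_alive` and a
#'   `Total` row.
#' @export
survival_summary <- function(counts) {
  req <- c("label", "n_grafted", "n_remaining")
  if (!all(req %in% names(counts))) stop("missing required columns")
  if (any(counts$n_grafted < 0 | counts$n_remaining < 0))
    stop("counts must be non-negative")
  if (any(counts$n_remaining > counts$n_grafted))
    stop("`n_remaining` cannot exceed `n_grafted`")
  pct <- function(rem, tot) if (tot == 0) NA_real_ else
    floor(100 * rem / tot + 1e-9)
  out <- counts[, intersect(c("experiment", "label", "n_grafted",
                              "n_remaining"), names(counts))]
  out$percent_alive <- mapply(pct, counts$n_remaining, counts$n_grafted)
  total <- out[1L, , drop = FALSE]
  total[1L, ] <- NA
  total$label <- "Total"
  total$n_grafted <- sum(counts$n_grafted)
  total$n_remaining <- sum(counts$n_remaining)
  total$percent_alive <- pct(total$n_remaining, total$n_grafted)
  out <- rbind(out, total)
  class(out) <- c("survival_summary", "data.frame")
  out
}
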