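test_that("largest-remainder apportionment matches the 70/15/15 design", {
  fr <- c(train = 0.70, val = 0.15, test = 0.15)
  expect_equal(pearlrot:::apportion(20L, fr), c(14L, 3L, 3L))
  expect_equal(pearlrot:::apportion(47L, fr), c(33L, 7L, 7L))
  for (n in 1:40) expect_equal(sum(pearlrot:::apportion(n, fr)), n)
})

test_that("splits group by pearl, stratify by class and are reproducible", {
  pearls <- data.frame(
    pearl_id = sprintf("P%02d", 1:40),
    label = rep(pearl_classes(), length.out = 40)
  )
  plan <- grouped_stratified_split(pearls, seed = 1)
  expect_equal(sort(plan$pearl_id), sort(pearls$pearl_id)) # exactly one split each
  tab <- table(plan$label, plan$split)
  for (cl in rownames(tab)) {
    n_cl <- sum(tab[cl, ])
    expect_true(all(abs(tab[cl, c("train", "val", "test")] -
                          n_cl * c(0.7, 0.15, 0.15)) <= 1))
  }
  expect_identical(plan, grouped_stratified_split(pearls, seed = 1))
  expect_false(identical(plan$split,
                         grouped_stratified_split(pearls, seed = 2)$split))
  expect_error(grouped_stratified_split(pearls, fractions = c(0.6, 0.2, 0.1)),
               "sum to 1")
})

test_that("each pearl lands in the test split at the expected binomial rate", {
  pearls <- data.frame(pearl_id = sprintf("P%02d", 1:20),
                       label = rep("Round", 20))
  n_rep <- 100L
  seeds <- pearlrot:::derive_seeds(99L, n_rep)
  in_test <- sapply(seeds, function(s) {
    plan <- grouped_stratified_split(pearls, seed = s)
    plan$split[order(plan$pearl_id)] == "test"
  })
  freq <- rowMeans(in_test)
  bound <- 3 * sqrt(0.15 * 0.85 / n_rep)
  expect_true(all(abs(freq - 0.15) <= bound))
})

test_that("harvest groups are represented across splits where size permits", {
  pearls <- data.frame(
    pearl_id = sprintf("P%02d", 1:30),
    label = "Round",
    harvest_date_group = rep(c("early", "mid", "late"), each = 10)
  )
  plan <- grouped_stratified_split(pearls, seed = 3)
  grp <- pearls$harvest_date_group[match(plan$pearl_id, pearls$pearl_id)]
  # the dominant (train) split must contain every harvest group
  expect_setequal(unique(grp[plan$split == "train"]),
                  c("early", "mid", "late"))
})

test_that("classification metrics match a brute-force oracle", {
  # independent oracle: explicit per-class precision/recall counting
  oracle <- function(true, pred, classes) {
    f1 <- numeric(length(classes))
    for (i in seq_along(classes)) {
      tp <- sum(true == classes[i] & pred == classes[i])
      fp <- sum(true != classes[i] & pred == classes[i])
      fn <- sum(true == classes[i] & pred != classes[i])
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    support <- vapply(classes, function(cl) sum(true == cl), 0)
    list(acc = mean(true == pred), f1 = f1, macro = mean(f1),
         weighted = sum(f1 * support) / sum(support))
  }
  classes <- pearl_classes()
  set.seed(8)
  for (rep in 1:20) {
    true <- sample(classes, 60, replace = TRUE, prob = c(0.5, 0.2, 0.3))
    pred <- ifelse(stats::runif(60) < 0.6, true,
                   sample(classes, 60, replace = TRUE))
    m <- classification_metrics(true, pred)
    o <- oracle(true, pred, classes)
    expect_equal(m$accuracy, o$acc)
    expect_equal(c(m$f1_other, m$f1_atypical, m$f1_round), o$f1)
    expect_equal(m$macro_f1, o$macro)
    expect_equal(m$weighted_f1, o$weighted)
    expect_equal(m$macro_f1, mean(c(m$f1_other, m$f1_atypical, m$f1_round)))
  }
})

test_that("metric edge cases: perfection, balanced supports, printed example", {
  true <- rep(pearl_classes(), each = 4L)
  m <- classification_metrics(true, true)
  expect_equal(unlist(m), c(accuracy = 1, weighted_f1 = 1, macro_f1 = 1,
                            f1_other = 1, f1_atypical = 1, f1_round = 1))
  # equal supports: weighted F1 equals macro F1
  set.seed(4)
  pred <- sample(true)
  mb <- classification_metrics(true, pred)
  expect_equal(mb$weighted_f1, mb$macro_f1)
  # TP/FP/FN = (8,2,2) for one class gives F1 = 0.8
  true2 <- c(rep("Round", 10), rep("Other", 10))
  pred2 <- c(rep("Round", 8), rep("Other", 2), rep("Round", 2), rep("Other", 8))
  expect_equal(classification_metrics(true2, pred2)$f1_round,
               2 * 8 / (2 * 8 + 2 + 2))
  expect_error(classification_metrics(character(0), character(0)), "nonempty")
})

test_that("the published macro-average F1 values follow from the per-class triples", {
  ref <- reference_f1_table()
  recomputed <- rowMeans(ref[, c("f1_other", "f1_atypical", "f1_round")])
  # agreement to half a unit in the last printed digit
  printed_tol <- ifelse(ref$dataset == "full", 5e-3, 5e-4)
  expect_true(all(abs(recomputed - ref$macro_f1) <= printed_tol))
})

test_that("repeated holdout aggregates per-repeat metrics at both levels", {
  # features encode the label exactly: the head must reach perfect accuracy
  classes <- pearl_classes()
  n_pearls <- 24L
  labels <- rep(classes, each = n_pearls / 3L)
  ids <- sprintf("P%02d", seq_len(n_pearls))
  onehot <- diag(3L)[match(labels, classes), ] * 10
  d <- list(features = rbind(onehot, onehot), # two samples per pearl
            culture_days = rep(200, 2L * n_pearls),
            acq_offset_days = rep(40, 2L * n_pearls),
            labels = c(labels, labels), pearl_id = c(ids, ids))
  ds <- structure(list(
    samples = lapply(seq_along(d$labels), function(i) {
      structure(list(pearl_id = d$pearl_id[i], label = d$labels[i],
                     culture_days = 200, acq_offset_days = 40),
                class = "pearl_sample")
    }), variant = "week"), class = "pearl_dataset")
  ms <- repeated_holdout(ds, n_repeats = 3L, head = head_spec(8L, 0),
                         hyper = list(lr = 1e-2, epochs = 30L), seed = 5L,
                         features = d$features)
  expect_s3_class(ms, "metrics_summary")
  expect_equal(nrow(ms$per_repeat), 6L) # 3 repeats x 2 levels
  agg <- ms$aggregate
  expect_equal(agg$accuracy_mean[agg$level == "sample"], 1)
  expect_equal(agg$accuracy_sd[agg$level == "sample"], 0)
  expect_equal(agg$accuracy_mean[agg$level == "pearl"], 1)
  csv <- tempfile(fileext = ".csv")
  write_metrics_csv(ms, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(names(back), c("repeat", "level", "accuracy", "weighted_f1",
                              "macro_f1", "f1_other", "f1_atypical",
                              "f1_round"))
})

test_that("repeated holdout with a single repeat reduces to one split", {
  tr <- separable_samples(n_per_class = 7L)
  ds <- structure(list(
    samples = lapply(seq_along(tr$labels), function(i)
      structure(list(pearl_id = tr$pearl_id[i], label = tr$labels[i],
                     culture_days = 200, acq_offset_days = 50),
                class = "pearl_sample")), variant = "week"),
    class = "pearl_dataset")
  ms <- repeated_holdout(ds, n_repeats = 1L, head = head_spec(8L, 0),
                         hyper = list(epochs = 10L), seed = 2L,
                         features = tr$features)
  expect_equal(unique(ms$per_repeat$repeat_index), 1L)
})

test_that("grid search picks the best configuration with deterministic tie-breaks", {
  tr <- separable_samples(n_per_class = 8L)
  va <- separable_samples(n_per_class = 4L, seed = 9)
  single <- grid_search(tr, va, grid = data.frame(lr = 1e-2, epochs = 20L),
                        head = head_spec(8L, 0))
  expect_equal(single$best$lr, 1e-2)
  # a dead learning rate can never win on separable data
  grid <- data.frame(lr = c(1e-12, 1e-2), epochs = c(20L, 20L))
  res <- grid_search(tr, va, grid = grid, head = head_spec(8L, 0))
  expect_equal(res$best$lr, 1e-2)
  res2 <- grid_search(tr, va, grid = grid, head = head_spec(8L, 0))
  expect_equal(res$results$val_acc, res2$results$val_acc)
  expect_error(grid_search(tr, va, grid = list()), "empty grid")
})

test_that("survival summaries reproduce the printed retention arithmetic", {
  expect_equal(survival_summary(data.frame(
    label = "Medium", n_grafted = 50, n_remaining = 38))$percent_alive[1L], 76)
  expect_equal(survival_summary(data.frame(
    label = "Poor", n_grafted = 20, n_remaining = 0))$percent_alive[1L], 0)
  expect_equal(survival_summary(data.frame(
    label = "x", n_grafted = 7, n_remaining = 7))$percent_alive[1L], 100)
  ref <- reference_survival_table()
  out <- survival_summary(ref[, c("experiment", "label", "n_grafted",
                                  "n_remaining")])
  body <- out[out$label != "Total", ]
  expect_equal(body$percent_alive, ref$percent_alive)
  total <- out[out$label == "Total", ]
  expect_equal(total$n_remaining, sum(ref$n_remaining))
  expect_error(survival_summary(data.frame(label = "a", n_grafted = 2,
                                           n_remaining = 5)), "exceed")
  expect_error(survival_summary(data.frame(label = "a", n_grafted = -1,
                                           n_remaining = 0)), "negative")
})
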