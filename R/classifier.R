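# Shape classification: frozen convolutional feature extraction, fusion of
# the two cultivation-metadata scalars, and a trained dense/dropout/softmax
# head with per-sample and per-pearl prediction.
#
# Two backbones are specified. "vgg16-frozen" is the transfer-learning
# configuration (ImageNet-pretrained VGG-16 convolutional base, 25088-dim
# flattened final max-pool output); it needs externally supplied weights via
# an extractor closure. "tiny-cnn" is a small frozen convolutional stack with
# fixed-seed random weights: random convolutional features are a well-studied
# baseline and make the whole pipeline testable offline.

TINY_CNN_SEED <- 1021L # frozen forever; changing it changes every feature

#' Backbone specification
#'
#' @param name `"tiny-cnn"` or `"vgg16-frozen"`.
#' @param extractor for `"vgg16-frozen"`, a function(image) -> numeric vector
#'   wrapping an external pretrained feature extractor.
#' @return a `backbone_spec` with `name`, `output_dim`, `deterministic`, and
#'   for tiny-cnn the frozen weights.
#' @export
backbone_spec <- function(name = c("tiny-cnn", "vgg16-frozen"),
                          extractor = NULL) {
  name <- match.arg(name)
  if (name == "vgg16-frozen") {
    # 224 / 2^5 = 7 after the five max-pool layers; 7 * 7 * 512 = 25088
    return(structure(
      list(name = name, input_size = 224L, output_dim = 25088L,
           deterministic = TRUE, extractor = extractor),
      class = "backbone_spec"
    ))
  }
  weights <- with_seed(TINY_CNN_SEED, {
    he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
    list(
      W1 = matrix(he(27, 27 * 8), 27, 8),   b1 = rep(0, 8),
      W2 = matrix(he(72, 72 * 16), 72, 16), b2 = rep(0, 16)
    )
  })
  structure(
    list(name = name, input_size = 224L, output_dim = 7L * 7L * 16L,
         deterministic = TRUE, weights = weights),
    class = "backbone_spec"
  )
}

# Block average-pool an h x w x c array by factor k (h, w divisible by k).
avg_pool <- function(x, k) {
  d <- dim(x)
  blocks <- vector("list", k * k)
  idx <- 1L
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    blocks[[idx]] <- x[seq(1L + dr, d[1L], by = k),
                       seq(1L + dc, d[2L], by = k), , drop = FALSE]
    idx <- idx + 1L
  }
  Reduce(`+`, blocks) / (k * k)
}

max_pool <- function(x, k) {
  d <- dim(x)
  out <- NULL
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    blk <- x[seq(1L + dr, d[1L], by = k), seq(1L + dc, d[2L], by = k), ,
             drop = FALSE]
    out <- if (is.null(out)) blk else pmax(out, blk)
  }
  out
}

# 3x3 same-padding convolution via im2col. x: h x w x cin array;
# W: (9 * cin) x cout; returns h x w x cout.
conv3x3_same <- function(x, W, b) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; cin <- d[3L]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  col <- 1L
  for (ch in seq_len(cin)) {
    for (dc in 0:2) for (dr in 0:2) {
      cols[, col] <- as.numeric(xp[(1L + dr):(h + dr), (1L + dc):(w + dc), ch])
      col <- col + 1L
    }
  }
  out <- sweep(cols %*% W, 2L, b, "+")
  array(out, c(h, w, ncol(W)))
}

relu <- function(x) pmax(x, 0)

tiny_cnn_forward <- function(img, weights) {
  x <- img / 255 - 0.5
  x <- avg_pool(x, 4L)                          # 224 -> 56
  x <- relu(conv3x3_same(x, weights$W1, weights$b1))
  x <- max_pool(x, 2L)                          # 56 -> 28
  x <- relu(conv3x3_same(x, weights$W2, weights$b2))
  x <- max_pool(x, 4L)                          # 28 -> 7
  as.numeric(x)                                 # 7 * 7 * 16 = 784
}

#' Extract frozen convolutional features from an image
#'
#' Deterministic feature map: the backbone is never trained, so identical
#' images always give identical features.
#'
#' @param image `size x size x 3` array, RGB 0-255.
#' @param backbone a [backbone_spec()].
#' @return numeric vector of length `backbone$output_dim`.
#' @export
extract_features <- function(image, backbone = backbone_spec("tiny-cnn")) {
  stopifnot(inherits(backbone, "backbone_spec"))
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L || d[1L] != backbone$input_size ||
      d[2L] != backbone$input_size)
    stop(sprintf("image must be %d x %d x 3", backbone$input_size,
                 backbone$input_size))
  if (backbone$name == "vgg16-frozen") {
    if (is.null(backbone$extractor))
      stop(paste("the vgg16-frozen backbone needs pretrained weights:",
                 "supply an `extractor` closure to backbone_spec()"))
    f <- backbone$extractor(image)
    if (length(f) != backbone$output_dim)
      stop("extractor returned the wrong feature dimension")
    return(as.numeric(f))
  }
  tiny_cnn_forward(image, backbone$weights)
}

#' Extract features for every sample of a dataset
#'
#' @param dataset a `pearl_dataset`.
#' @param backbone a [backbone_spec()].
#' @return `n x output_dim` feature matrix, rows in sample order.
#' @export
extract_features_dataset <- function(dataset,
                                     backbone = backbone_spec("tiny-cnn")) {
  stopifnot(inherits(dataset, "pearl_dataset"))
  t(vapply(dataset$samples, function(s)
    extract_features(s$image, backbone), numeric(backbone$output_dim)))
}

#' Fit the metadata normalizer
#'
#' Per-feature mean and SD of the two cultivation scalars, computed on the
#' training split only.
#'
#' @param culture_days,acq_offset_days training-split metadata vectors.
#' @return a `metadata_normalizer` with `mean` and `sd` (length 2).
#' @export
metadata_normalizer <- function(culture_days, acq_offset_days) {
  m <- c(mean(culture_days), mean(acq_offset_days))
  s <- c(stats::sd(culture_days), stats::sd(acq_offset_days))
  s[!is.finite(s) | s < 1e-8] <- 1
  structure(list(mean = m, sd = s), class = "metadata_normalizer")
}

#' Fuse image features with the two metadata scalars
#'
#' Appends the z-scored cultivation-day and acquisition-offset scalars to the
#' image feature vector (fused dimension = feature dimension + 2). The
#' weighting of the two scalars is learned by the first dense layer of the
#' head.
#'
#' @param features numeric vector or `n x d` matrix of image features.
#' @param culture_days,acq_offset_days metadata scalar(s).
#' @param normalizer a fitted [metadata_normalizer()].
#' @return fused vector or matrix of width `d + 2`.
#' @export
fuse_metadata <- function(features, culture_days, acq_offset_days,
                          normalizer) {
  if (!inherits(normalizer, "metadata_normalizer"))
    stop("`normalizer` must be a fitted metadata_normalizer")
  z1 <- (culture_days - normalizer$mean[1L]) / normalizer$sd[1L]
  z2 <- (acq_offset_days - normalizer$mean[2L]) / normalizer$sd[2L]
  if (is.matrix(features)) cbind(features, z1, z2, deparse.level = 0)
  else c(features, z1, z2)
}

#' Classifier head specification
#'
#' Dense/dropout stack ending in a 3-way softmax.
#'
#' @param dense_widths widths of the hidden dense layers.
#' @param dropout_rates dropout fraction after each hidden layer, in \[0, 1).
#' @param n_classes number of classes (fixed at 3).
#' @param metadata_dim number of fused metadata scalars (fixed at 2).
#' @return a `head_spec`.
#' @export
head_spec <- function(dense_widths = 256L, dropout_rates = 0.5,
                      n_classes = 3L, metadata_dim = 2L) {
  if (length(dropout_rates) == 1L)
    dropout_rates <- rep(dropout_rates, length(dense_widths))
  if (length(dropout_rates) != length(dense_widths))
    stop("`dropout_rates` must match `dense_widths`")
  if (any(dropout_rates < 0 | dropout_rates >= 1))
    stop("dropout rates must be in [0, 1)")
  structure(
    list(dense_widths = as.integer(dense_widths),
         dropout_rates = dropout_rates, n_classes = as.integer(n_classes),
         metadata_dim = as.integer(metadata_dim)),
    class = "head_spec"
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

head_forward <- function(params, X, dropout_masks = NULL) {
  H <- X
  acts <- list(H)
  for (l in seq_along(params$W)[-length(params$W)]) {
    H <- relu(sweep(H %*% params$W[[l]], 2L, params$b[[l]], "+"))
    if (!is.null(dropout_masks)) H <- H * dropout_masks[[l]]
    acts[[l + 1L]] <- H
  }
  L <- length(params$W)
  logits <- sweep(H %*% params$W[[L]], 2L, params$b[[L]], "+")
  list(probs = softmax_rows(logits), acts = acts)
}

# Prepare (features, metadata, labels, pearl_ids) from a pearl_dataset or a
# pre-extracted list.
prepare_samples <- function(data, backbone, features = NULL) {
  if (inherits(data, "pearl_dataset")) {
    feats <- features %||% extract_features_dataset(data, backbone)
    list(
      features = feats,
      culture_days = vapply(data$samples, `[[`, 0, "culture_days"),
      acq_offset_days = vapply(data$samples, `[[`, 0, "acq_offset_days"),
      labels = vapply(data$samples, `[[`, "", "label"),
      pearl_id = vapply(data$samples, `[[`, "", "pearl_id")
    )
  } else {
    stopifnot(is.list(data), !is.null(data$features), !is.null(data$labels))
    data
  }
}

#' Train the classification head
#'
#' Fits only the head parameters (the backbone stays frozen) with Adam on
#' cross-entropy, inverted dropout, and early stopping on validation
#' accuracy (the best epoch's weights are kept). The metadata normalizer and
#' feature scaler are fitted on the training split only. Deterministic under
#' a fixed seed.
#'
#' @param train,val `pearl_dataset`s, or lists with elements `features`
#'   (matrix), `culture_days`, `acq_offset_days`, `labels`, `pearl_id`.
#' @param head a [head_spec()].
#' @param hyper list of hyperparameters: `lr` (1e-3), `epochs` (30),
#'   `batch` (16), `seed` (1).
#' @param backbone a [backbone_spec()] (used to extract features when
#'   datasets are passed, and stored for prediction).
#' @return a `pearl_model`.
#' @export
train_classifier <- function(train, val, head = head_spec(),
                             hyper = list(), backbone = backbone_spec("tiny-cnn")) {
  hyper <- utils::modifyList(
    list(lr = 1e-3, epochs = 30L, batch = 16L, seed = 1L), hyper)
  tr <- prepare_samples(train, backbone)
  va <- prepare_samples(val, backbone)
  classes <- pearl_classes()
  missing_cls <- setdiff(classes, unique(tr$labels))
  if (length(missing_cls))
    warning("class(es) absent from training split: ",
            paste(missing_cls, collapse = ", "))

  norm <- metadata_normalizer(tr$culture_days, tr$acq_offset_days)
  fmean <- colMeans(tr$features)
  fsd <- apply(tr$features, 2L, stats::sd)
  fsd[!is.finite(fsd) | fsd < 1e-8] <- 1
  scaler <- list(mean = fmean, sd = fsd)

  fuse_scale <- function(d) {
    F <- sweep(sweep(d$features, 2L, scaler$mean), 2L, scaler$sd, "/")
    fuse_metadata(F, d$culture_days, d$acq_offset_days, norm)
  }
  Xtr <- fuse_scale(tr)
  Xva <- fuse_scale(va)
  ytr <- factor(tr$labels, levels = classes)
  yva <- factor(va$labels, levels = classes)
  Ytr <- diag(length(classes))[as.integer(ytr), , drop = FALSE]

  dims <- c(ncol(Xtr), head$dense_widths, head$n_classes)
  n <- nrow(Xtr)

  fitted <- with_seed(hyper$seed, {
    params <- list(W = list(), b = list())
    for (l in seq_len(length(dims) - 1L)) {
      params$W[[l]] <- matrix(
        stats::rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / dims[l])),
        dims[l], dims[l + 1L])
      params$b[[l]] <- rep(0, dims[l + 1L])
    }
    mW <- lapply(params$W, function(w) w * 0); vW <- mW
    mb <- lapply(params$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- data.frame(epoch = integer(), train_acc = numeric(),
                          val_acc = numeric())
    best <- list(acc = -Inf, params = params, epoch = 0L)
    nb <- length(params$W)

    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = hyper$batch)) {
        idx <- ord[start:min(start + hyper$batch - 1L, n)]
        X <- Xtr[idx, , drop = FALSE]
        Y <- Ytr[idx, , drop = FALSE]
        masks <- lapply(seq_along(head$dense_widths), function(l) {
          p <- head$dropout_rates[l]
          if (p <= 0) return(matrix(1, length(idx), head$dense_widths[l]))
          keep <- matrix(stats::runif(length(idx) * head$dense_widths[l]) >= p,
                         length(idx))
          keep / (1 - p)
        })
        fw <- head_forward(params, X, masks)
        delta <- (fw$probs - Y) / length(idx)
        for (l in rev(seq_len(nb))) {
          A <- fw$acts[[l]]
          gW <- t(A) %*% delta
          gb <- colSums(delta)
          if (l > 1L) {
            back <- delta %*% t(params$W[[l]])
            back <- back * (fw$acts[[l]] > 0) * masks[[l - 1L]]
            delta <- back
          }
          step_l <- step + 1L
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          mhW <- mW[[l]] / (1 - b1^step_l); vhW <- vW[[l]] / (1 - b2^step_l)
          mhb <- mb[[l]] / (1 - b1^step_l); vhb <- vb[[l]] / (1 - b2^step_l)
          params$W[[l]] <- params$W[[l]] - hyper$lr * mhW / (sqrt(vhW) + eps)
          params$b[[l]] <- params$b[[l]] - hyper$lr * mhb / (sqrt(vhb) + eps)
        }
        step <- step + 1L
      }
      pred_tr <- classes[max.col(head_forward(params, Xtr)$probs, "first")]
      pred_va <- classes[max.col(head_forward(params, Xva)$probs, "first")]
      tr_acc <- mean(pred_tr == as.character(ytr))
      va_acc <- mean(pred_va == as.character(yva))
      history <- rbind(history, data.frame(epoch = epoch, train_acc = tr_acc,
                                           val_acc = va_acc))
      if (va_acc > best$acc) best <- list(acc = va_acc, params = params,
                                          epoch = epoch)
    }
    list(params = best$params, history = history, best_epoch = best$epoch)
  })

  structure(
    list(backbone = backbone, head = head, params = fitted$params,
         normalizer = norm, feature_scaler = scaler, classes = classes,
         history = fitted$history, best_epoch = fitted$best_epoch,
         hyper = hyper),
    class = "pearl_model"
  )
}

#' @export
print.pearl_model <- function(x, ...) {
  cat(sprintf(
    "<pearl_model> %s backbone, head %s, best epoch %d (val acc %.3f)\n",
    x$backbone$name, paste(x$head$dense_widths, collapse = "-"),
    x$best_epoch, max(x$history$val_acc)))
  invisible(x)
}

model_input <- function(model, features, culture_days, acq_offset_days) {
  if (is.null(dim(features))) features <- matrix(features, 1L)
  F <- sweep(sweep(features, 2L, model$feature_scaler$mean), 2L,
             model$feature_scaler$sd, "/")
  fuse_metadata(F, culture_days, acq_offset_days, model$normalizer)
}

#' Predict class probabilities for one sample
#'
#' @param model a trained `pearl_model`.
#' @param sample a `pearl_sample`, or a list with `features`,
#'   `culture_days`, `acq_offset_days`.
#' @return named probability 3-vector (sums to 1).
#' @export
predict_sample <- function(model, sample) {
  stopifnot(inherits(model, "pearl_model"))
  if (inherits(sample, "pearl_sample")) {
    feats <- extract_features(sample$image, model$backbone)
    meta <- c(sample$culture_days, sample$acq_offset_days)
  } else {
    feats <- sample$features
    meta <- c(sample$culture_days, sample$acq_offset_days)
  }
  X <- model_input(model, feats, meta[1L], meta[2L])
  p <- drop(head_forward(model$params, X)$probs)
  names(p) <- model$classes
  p
}

#' Predict probabilities for every sample of a dataset
#'
#' @param model a trained `pearl_model`.
#' @param dataset a `pearl_dataset`.
#' @param features optional pre-extracted feature matrix (rows in sample
#'   order) to avoid re-running the backbone.
#' @return list with `probs` (n x 3 matrix), `pred` (character), `pearl_id`,
#'   `label`.
#' @export
predict_dataset <- function(model, dataset, features = NULL) {
  d <- prepare_samples(dataset, model$backbone, features = features)
  X <- model_input(model, d$features, d$culture_days, d$acq_offset_days)
  probs <- head_forward(model$params, X)$probs
  colnames(probs) <- model$classes
  list(probs = probs, pred = model$classes[max.col(probs, "first")],
       pearl_id = d$pearl_id, label = d$labels)
}

#' Per-pearl majority-vote prediction
#'
#' Predicts each weekly sample of one pearl and retains the most frequent
#' class; ties are broken by the highest mean probability among the tied
#' classes (then by fixed class order).
#'
#' @param model a trained `pearl_model`.
#' @param samples list of `pearl_sample`s from a single pearl, or a
#'   pre-computed probability matrix (columns named by class).
#' @return the predicted class (character scalar).
#' @export
predict_pearl <- function(model, samples) {
  if (is.matrix(samples)) {
    probs <- samples
  } else {
    ids <- unique(vapply(samples, `[[`, "", "pearl_id"))
    if (length(ids) != 1L) stop("samples come from more than one pearl")
    probs <- t(vapply(samples, function(s) predict_sample(model, s),
                      numeric(length(model$classes))))
  }
  vote_pearl(probs, model$classes)
}

# Majority vote with mean-probability tie-break on a probability matrix.
vote_pearl <- function(probs, classes) {
  pred <- classes[max.col(probs, "first")]
  tab <- table(factor(pred, levels = classes))
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  mp <- colMeans(probs[, top, drop = FALSE])
  top[which.max(mp)]
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a directory of portable text artifacts: head weights
#' (JSON, full precision), metadata normalizer and feature scaler (JSON),
#' backbone spec (JSON; tiny-cnn weights are regenerated from their frozen
#' seed), and the training history CSV (`epoch,train_acc,val_acc`).
#'
#' @param model a `pearl_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` a
#'   `pearl_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "pearl_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jwrite <- function(x, f)
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA),
               file.path(dir, f))
  jwrite(list(W = model$params$W, b = model$params$b), "head_weights.json")
  jwrite(list(metadata_mean = model$normalizer$mean,
              metadata_sd = model$normalizer$sd,
              feature_mean = model$feature_scaler$mean,
              feature_sd = model$feature_scaler$sd), "normalizer.json")
  jwrite(list(backbone = model$backbone$name,
              output_dim = model$backbone$output_dim,
              classes = model$classes,
              dense_widths = model$head$dense_widths,
              dropout_rates = model$head$dropout_rates,
              hyper = model$hyper[c("lr", "epochs", "batch", "seed")],
              best_epoch = model$best_epoch), "model_spec.json")
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  jread <- function(f) jsonlite::fromJSON(file.path(dir, f),
                                          simplifyMatrix = TRUE)
  spec <- jread("model_spec.json")
  wts <- jread("head_weights.json")
  nrm <- jread("normalizer.json")
  params <- list(W = lapply(wts$W, as.matrix),
                 b = lapply(wts$b, as.numeric))
  structure(
    list(
      backbone = backbone_spec(spec$backbone),
      head = head_spec(spec$dense_widths, spec$dropout_rates),
      params = params,
      normalizer = structure(list(mean = nrm$metadata_mean,
                                  sd = nrm$metadata_sd),
                             class = "metadata_normalizer"),
      feature_scaler = list(mean = nrm$feature_mean, sd = nrm$feature_sd),
      classes = spec$classes,
      history = utils::read.csv(file.path(dir, "history.csv")),
      best_epoch = spec$best_epoch,
      hyper = spec$hyper
    ),
    class = "pearl_model"
  )
}
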