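#' Training configuration
#'
#' Defaults follow the study protocol where stated (Adam, batch size 16)
#' and desk-scale values elsewhere; the protocol-scale settings (300
#' epochs, 10 folds, 6x augmentation) are reachable by argument.
#'
#' @param epochs training epochs (protocol value 300; default here is a
#'   desk-scale 20).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param augment_factor augmented copies generated per training sample
#'   (default 6); the originals are kept alongside.
#' @param k_folds folds for [cross_validate()] (default 10).
#' @param val_fraction fraction of each fold's training portion held out
#'   as the checkpoint-selection validation set (default 0.1).
#' @param seed RNG seed governing fold assignment, validation split,
#'   augmentation, weight init, shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 16, learning_rate = 1e-3,
                         augment_factor = 6, k_folds = 10,
                         val_fraction = 0.1, seed = 1L) {
  if (!is.numeric(epochs) || epochs < 1) stop_field("epochs", "must be >= 1")
  if (!is.numeric(batch_size) || batch_size < 1)
    stop_field("batch_size", "must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_field("learning_rate", "must be > 0")
  if (!is.numeric(augment_factor) || augment_factor < 0)
    stop_field("augment_factor", "must be >= 0")
  if (!is.numeric(k_folds) || k_folds < 2) stop_field("k_folds", "must be >= 2")
  if (!is.numeric(val_fraction) || val_fraction <= 0 || val_fraction >= 1)
    stop_field("val_fraction", "must be in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 augment_factor = as.integer(augment_factor),
                 k_folds = as.integer(k_folds),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Draw a random augmentation transform
#'
#' Samples one composition of horizontal/vertical flip (each with
#' probability 0.5), rotation (uniform +/-25 degrees), zoom (0.85--1.15),
#' brightness scale (0.8--1.2) and gamma correction (0.7--1.4). The
#' geometric part is applied identically to image and mask; the
#' photometric part touches the image only.
#'
#' @return a named list describing the transform.
#' @export
random_transform <- function() {
  list(flip_h = runif(1) < 0.5,
       flip_v = runif(1) < 0.5,
       angle = runif(1, -25, 25),
       zoom = runif(1, 0.85, 1.15),
       brightness = runif(1, 0.8, 1.2),
       gamma = runif(1, 0.7, 1.4))
}

# inverse-mapped affine (rotation + zoom about the image centre); bilinear
# for image channels, nearest-neighbour for the mask, edge-clamped
.warp_affine <- function(img, mask, angle, zoom) {
  H <- nrow(mask); W <- ncol(mask)
  if (abs(angle) < 1e-9 && abs(zoom - 1) < 1e-9)
    return(list(image = img, mask = mask))
  th <- -angle * pi / 180          # inverse rotation
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W) - cy
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sr <- (cos(th) * rows - sin(th) * cols) / zoom + cy
  sc <- (sin(th) * rows + cos(th) * cols) / zoom + cx
  sr <- pmin(pmax(sr, 1), H)
  sc <- pmin(pmax(sc, 1), W)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c1))
  i10 <- cbind(as.vector(r1), as.vector(c0))
  i11 <- cbind(as.vector(r1), as.vector(c1))
  w00 <- as.vector((1 - fr) * (1 - fc)); w01 <- as.vector((1 - fr) * fc)
  w10 <- as.vector(fr * (1 - fc));       w11 <- as.vector(fr * fc)
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    M <- img[, , ch]
    out[, , ch] <- matrix(M[i00] * w00 + M[i01] * w01 +
                            M[i10] * w10 + M[i11] * w11, H, W)
  }
  inn <- cbind(as.vector(round(sr)), as.vector(round(sc)))
  list(image = out, mask = matrix(as.integer(mask[inn] > 0), H, W))
}

#' Apply an augmentation transform to a sample
#'
#' @param sample a dataset sample (`image`, `mask`, `is_positive`).
#' @param tr a transform from [random_transform()]; individual components
#'   may be overridden for deterministic testing.
#' @return the transformed sample; the mask stays binary and image
#'   intensities are clipped back to \[0, 1\].
#' @export
apply_transform <- function(sample, tr) {
  img <- sample$image
  mask <- sample$mask
  if (isTRUE(tr$flip_h)) {          # mirror columns
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (isTRUE(tr$flip_v)) {          # mirror rows
    img <- img[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  w <- .warp_affine(img, mask, tr$angle %||% 0, tr$zoom %||% 1)
  img <- w$image
  img <- img * (tr$brightness %||% 1)
  img <- clip01(img)^(tr$gamma %||% 1)
  list(image = img, mask = w$mask, is_positive = any(w$mask == 1L))
}

#' Generate augmented copies of a sample
#'
#' @param sample a dataset sample.
#' @param n number of augmented copies (0 gives an empty list).
#' @param seed optional seed for reproducibility.
#' @return list of `n` augmented samples.
#' @export
augment_sample <- function(sample, n, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  with_seed(seed,
    lapply(seq_len(n), function(i) apply_transform(sample, random_transform())))
}

# ---- Adam optimizer ---------------------------------------------------------

.adam_init <- function(params) {
  z <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
  list(m = z, v = z, t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# mean deterministic-mode cross-entropy over a sample list
.eval_loss <- function(model, samples) {
  mean(vapply(samples, function(s) {
    fw <- unet_forward(model, s$image, mode = "off")
    ce_loss_grad(fw$probs, s$mask, grad = FALSE)$loss
  }, numeric(1)))
}

#' Train a model with validation-loss checkpointing
#'
#' Minibatch Adam on pixel-wise cross-entropy. Dropout is active in
#' training mode; validation loss is computed with dropout off
#' (deterministic), and the best checkpoint is the one after the epoch
#' with the minimum validation loss seen so far (strict-decrease update).
#'
#' @param model a [build_model()] result (used as initialization).
#' @param train_samples nonempty list of training samples.
#' @param val_samples nonempty list of validation samples.
#' @param config a [train_config()]; `k_folds`/`augment_factor` are not
#'   used here (see [cross_validate()]). `config$seed` (if non-NULL)
#'   makes shuffling and dropout reproducible.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `history` (data.frame of
#'   per-epoch `train_loss`/`val_loss`), `best_epoch`, `best_val_loss`.
#' @export
train_model <- function(model, train_samples, val_samples, config,
                        verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(train_samples) == 0)
    stop_field("train_samples", "training set is empty")
  if (length(val_samples) == 0)
    stop_field("val_samples", "validation set is empty")
  n <- length(train_samples)
  run <- function() {
    params <- model$params
    state <- .adam_init(params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(params = params, val = Inf, epoch = 0L)
    work <- model
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1, n)]
        grads <- NULL
        for (id in ids) {
          s <- train_samples[[id]]
          work$params <- params
          fw <- unet_forward(work, s$image, mode = "train", keep_cache = TRUE)
          lg <- ce_loss_grad(fw$probs, s$mask)
          ep_loss <- ep_loss + lg$loss
          g <- .unet_backward(work, fw$cache, lg$dlogits)
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(g) g / length(ids))
        upd <- .adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      work$params <- params
      tl <- ep_loss / n
      vl <- .eval_loss(work, val_samples)
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = tl, val_loss = vl))
      if (vl < best$val) best <- list(params = params, val = vl, epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f%s", ep, tl, vl,
                        if (best$epoch == ep) "  *" else ""))
    }
    work$params <- best$params
    list(model = work, history = history,
         best_epoch = best$epoch, best_val_loss = best$val)
  }
  with_seed(config$seed, run())
}

#' K-fold cross-validation of the full pipeline
#'
#' Splits the dataset into `k_folds` seeded random folds. For each fold,
#' the remaining samples are split again into a training portion and a
#' `val_fraction` validation portion (checkpoint selection); the training
#' portion is augmented `augment_factor` times (originals kept, test and
#' validation samples never augmented), a fresh model is trained, and the
#' held-out fold is evaluated with pixel counts pooled over its images
#' (micro-average).
#'
#' @param dataset list of samples.
#' @param config a [train_config()].
#' @param model_cfg a [model_config()].
#' @param sigma Monte Carlo samples for test-time prediction; `0` predicts
#'   deterministically (dropout off), `>= 1` predicts from the posterior
#'   mean of `sigma` dropout samples and also yields uncertainty maps.
#' @param keep_predictions keep per-image predicted labels and normalized
#'   uncertainty maps in each fold report.
#' @param keep_models keep each fold's best model in its report.
#' @param verbose print progress.
#' @return an object of class `cv_result`: `folds` (per-fold reports with
#'   `fold_index`, `test_indices`, `metrics`, `history`, `best_epoch`) and
#'   `aggregate` (mean and sd across folds of pixel accuracy, mean IoU,
#'   weighted IoU and Dice).
#' @export
cross_validate <- function(dataset, config, model_cfg, sigma = 0,
                           keep_predictions = FALSE, keep_models = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), inherits(model_cfg, "model_config"))
  n <- length(dataset)
  k <- config$k_folds
  if (k > n)
    stop_field("k_folds", sprintf("more folds (%d) than samples (%d)", k, n))
  fold_of <- with_seed(config$seed,
                       rep_len(seq_len(k), n)[sample(n)])
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    fseed <- config$seed + f * 9973L
    test_idx <- which(fold_of == f)
    pool <- which(fold_of != f)
    parts <- with_seed(fseed, {
      nv <- max(1L, round(config$val_fraction * length(pool)))
      val_idx <- sample(pool, nv)
      list(val = val_idx, train = setdiff(pool, val_idx))
    })
    train_set <- dataset[parts$train]
    if (config$augment_factor > 0) {
      aug <- with_seed(fseed + 1L, unlist(lapply(train_set, augment_sample,
                                                 n = config$augment_factor),
                                          recursive = FALSE))
      train_set <- c(train_set, aug)
    }
    model0 <- build_model(model_cfg, seed = fseed + 2L)
    fc <- config
    fc$seed <- fseed + 3L
    if (verbose)
      message(sprintf("fold %d/%d: train %d (incl. augmented) / val %d / test %d",
                      f, k, length(train_set), length(parts$val),
                      length(test_idx)))
    tr <- train_model(model0, train_set, dataset[parts$val], fc,
                      verbose = verbose)
    preds <- lapply(seq_along(test_idx), function(j) {
      s <- dataset[[test_idx[j]]]
      if (sigma >= 1) {
        mp <- mc_predict(tr$model, s$image, sigma = sigma,
                         seed = fseed + 10L + j)
        list(labels = mp$label_mask, uncertainty = mp$uncertainty_map)
      } else {
        fw <- unet_forward(tr$model, s$image, mode = "off")
        list(labels = predict_labels(fw$probs), uncertainty = NULL)
      }
    })
    gts <- lapply(dataset[test_idx], `[[`, "mask")
    metrics <- segmentation_metrics(lapply(preds, `[[`, "labels"), gts,
                                    n_classes = model_cfg$n_classes)
    folds[[f]] <- list(fold_index = f,
                       test_indices = test_idx,
                       metrics = metrics,
                       history = tr$history,
                       best_epoch = tr$best_epoch,
                       best_val_loss = tr$best_val_loss,
                       predictions = if (keep_predictions) preds,
                       model = if (keep_models) tr$model)
  }
  metric_names <- c("pixel_accuracy", "mean_iou", "weighted_iou", "dice")
  vals <- sapply(metric_names, function(mn)
    vapply(folds, function(fr) fr$metrics[[mn]], numeric(1)))
  vals <- matrix(vals, nrow = k, dimnames = list(NULL, metric_names))
  aggregate <- data.frame(metric = metric_names,
                          mean = apply(vals, 2, mean, na.rm = TRUE),
                          sd = apply(vals, 2, sd, na.rm = TRUE),
                          row.names = NULL)
  structure(list(folds = folds, aggregate = aggregate,
                 train_config = config, model_config = model_cfg,
                 sigma = sigma),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, sigma=%g\n", length(x$folds), x$sigma))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
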