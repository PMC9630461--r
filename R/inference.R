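#' Monte Carlo dropout sampling
#'
#' Runs `sigma` independent stochastic forward passes with dropout active
#' (the Bayesian approximation: each pass realizes one draw of the network
#' weights through its Bernoulli dropout masks) and stacks the softmax
#' outputs.
#'
#' @param model a trained `unet_model`.
#' @param image H x W x C image array.
#' @param sigma number of samples (>= 1; the study protocol uses 100).
#' @param seed optional seed; the full stack is reproducible given it.
#' @return an H x W x n_classes x sigma array of softmax samples.
#' @export
mc_sample <- function(model, image, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 1)
    stop_field("sigma", "must be a count >= 1")
  sigma <- as.integer(sigma)
  if (model$config$dropout_placement == "none")
    warning("model has no dropout layers; MC samples will be identical",
            call. = FALSE)
  with_seed(seed, {
    first <- unet_forward(model, image, mode = "mc")$probs
    out <- array(0, dim = c(dim(first), sigma))
    out[, , , 1] <- first
    if (sigma > 1)
      for (i in 2:sigma)
        out[, , , i] <- unet_forward(model, image, mode = "mc")$probs
    out
  })
}

#' Posterior-mean probability map
#'
#' Arithmetic mean of the sampled softmax outputs per pixel and class --
#' the Monte Carlo estimate of the predictive posterior mean.
#'
#' @param samples H x W x C x sigma stack from [mc_sample()].
#' @return H x W x C mean probability array.
#' @export
posterior_mean <- function(samples) {
  d <- dim(samples)
  if (is.null(d) || length(d) != 4 || d[4] < 1)
    stop_field("samples", "must be a nonempty H x W x C x sigma array")
  array(rowMeans(matrix(samples, ncol = d[4])), dim = d[1:3])
}

#' Per-pixel predictive variance
#'
#' Population variance (divide by sigma) of the sampled softmax outputs
#' around the posterior mean, computed per class and then averaged over
#' classes to one channel. For binary softmax both class channels carry
#' the same variance, so the reduction is lossless there.
#'
#' @param samples H x W x C x sigma stack.
#' @param mean_probs optional precomputed [posterior_mean()] of `samples`.
#' @return H x W nonnegative variance matrix; exactly zero everywhere iff
#'   all samples are identical.
#' @export
variance_map <- function(samples, mean_probs = NULL) {
  d <- dim(samples)
  if (is.null(d) || length(d) != 4 || d[4] < 1)
    stop_field("samples", "must be a nonempty H x W x C x sigma array")
  if (is.null(mean_probs)) mean_probs <- posterior_mean(samples)
  if (!identical(dim(mean_probs), d[1:3]))
    stop_field("mean_probs", "shape does not match samples")
  M <- matrix(samples, ncol = d[4])
  v <- rowMeans((M - as.vector(mean_probs))^2)      # per class, 1/sigma
  matrix(rowMeans(matrix(v, ncol = d[3])), d[1], d[2])
}

#' Min-max normalize an uncertainty map to \[0, 1\]
#'
#' @param v nonnegative variance matrix.
#' @return `(v - min) / (max - min)`; a constant map (no uncertainty
#'   signal, e.g. dropout disabled) maps to all zeros by convention.
#' @export
normalize_uncertainty <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-15) return(array(0, dim = dim(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Predicted label mask from a probability map
#'
#' @param mean_probs H x W x C probability array.
#' @return H x W integer matrix of 0-based class labels (per-pixel argmax;
#'   ties break toward the lower class index).
#' @export
predict_labels <- function(mean_probs) {
  d <- dim(mean_probs)
  matrix(max.col(matrix(mean_probs, ncol = d[3]), ties.method = "first") - 1L,
         d[1], d[2])
}

#' Full Monte Carlo dropout prediction
#'
#' Convenience wrapper: samples the model, reduces to the posterior mean,
#' the argmax label mask, the per-pixel variance and its \[0,1\]
#' normalization.
#'
#' @inheritParams mc_sample
#' @param keep_samples keep the raw sample stack in the result.
#' @return an object of class `mc_prediction` with `mean_probs`,
#'   `label_mask`, `variance_map`, `uncertainty_map`, `sigma`, and
#'   optionally `samples`.
#' @export
mc_predict <- function(model, image, sigma, seed = NULL, keep_samples = FALSE) {
  samples <- mc_sample(model, image, sigma, seed)
  mp <- posterior_mean(samples)
  vm <- variance_map(samples, mp)
  structure(list(mean_probs = mp,
                 label_mask = predict_labels(mp),
                 variance_map = vm,
                 uncertainty_map = normalize_uncertainty(vm),
                 sigma = as.integer(sigma),
                 samples = if (keep_samples) samples),
            class = "mc_prediction")
}

#' @export
print.mc_prediction <- function(x, ...) {
  d <- dim(x$mean_probs)
  cat(sprintf(
    "mc_prediction: %dx%d, %d classes, sigma=%d | lesion pixels=%d | mean uncertainty=%.4f\n",
    d[1], d[2], d[3], x$sigma, sum(x$label_mask != 0L),
    mean(x$uncertainty_map)))
  invisible(x)
}

#' Export prediction maps to disk
#'
#' Writes the label mask (0/255 PNG), the uncertainty map (linear
#' grayscale PNG, 0 to 255), a combined heatmap PNG (red: certain lesion;
#' dark blue: certain background; green: uncertain), and a lossless RDS
#' container with the numerical maps.
#'
#' @param prediction an [mc_predict()] result.
#' @param out_dir output directory, created if needed.
#' @param basename file name stem (default `"prediction"`).
#' @return named character vector of the written paths, invisibly.
#' @export
export_maps <- function(prediction, out_dir, basename = "prediction") {
  stopifnot(inherits(prediction, "mc_prediction"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  lab <- prediction$label_mask
  u <- prediction$uncertainty_map
  H <- nrow(lab); W <- ncol(lab)
  paths <- c(labels = file.path(out_dir, paste0(basename, "_labels.png")),
             uncertainty = file.path(out_dir, paste0(basename, "_uncertainty.png")),
             heatmap = file.path(out_dir, paste0(basename, "_heatmap.png")),
             maps = file.path(out_dir, paste0(basename, "_maps.rds")))
  png::writePNG(matrix(as.numeric(lab != 0L), H, W), paths[["labels"]])
  png::writePNG(u, paths[["uncertainty"]])
  fg <- as.numeric(lab != 0L)
  heat <- array(c(fg * (1 - u),               # red: certain lesion
                  as.vector(u),               # green: uncertain
                  (1 - fg) * (1 - u) * 0.6),  # blue: certain background
                dim = c(H, W, 3))
  png::writePNG(clip01(heat), paths[["heatmap"]])
  saveRDS(list(mean_probs = prediction$mean_probs,
               label_mask = prediction$label_mask,
               variance_map = prediction$variance_map,
               uncertainty_map = prediction$uncertainty_map,
               sigma = prediction$sigma),
          paths[["maps"]])
  invisible(paths)
}
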