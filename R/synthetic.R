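#' Parameters for the synthetic lesion-image generator
#'
#' The generator stands in for a clinical white-light photograph collection
#' that cannot be redistributed. It emulates the statistical structure the
#' segmentation method relies on: a skin-toned, textured background; in
#' positive samples, one or more irregular lesion blobs whose colour deviates
#' smoothly from the background so that the rendered border is diffuse while
#' the ground-truth mask boundary stays exact; and a positive/negative sample
#' mix (about 80/20 by default, matching a screening-style class balance).
#'
#' @param n_samples number of samples to generate.
#' @param positive_fraction fraction of samples that carry at least one
#'   lesion; allocation is deterministic, `round(positive_fraction * n)`.
#' @param image_size side length in pixels of the square images. The source
#'   imagery's resolution is not standardised, so this is a free choice;
#'   128 keeps desk-scale training practical.
#' @param lesion_count_range integer range (inclusive) for the number of
#'   lesions per positive image.
#' @param lesion_radius_range range of the nominal lesion radius in pixels.
#'   Defaults to 10--20% of `image_size`.
#' @param border_softness Gaussian blur scale (pixels) applied to the lesion
#'   field before rendering; larger values give more ambiguous borders. The
#'   ground-truth mask is thresholded *before* this blur, so the label
#'   boundary is exact while the image boundary is diffuse -- this is what
#'   makes border uncertainty an emergent property rather than an artefact.
#' @param noise_sd standard deviation of per-pixel Gaussian intensity noise.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   datasets.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_samples = 200,
                             positive_fraction = 0.8,
                             image_size = 128,
                             lesion_count_range = c(1L, 3L),
                             lesion_radius_range = NULL,
                             border_softness = 2.5,
                             noise_sd = 0.04,
                             seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1)
    stop_field("n_samples", "must be a single count >= 1")
  if (!is.numeric(positive_fraction) || length(positive_fraction) != 1 ||
      positive_fraction < 0 || positive_fraction > 1)
    stop_field("positive_fraction", "must be a probability in [0, 1]")
  if (!is.numeric(image_size) || length(image_size) != 1 || image_size < 16)
    stop_field("image_size", "must be >= 16")
  if (length(lesion_count_range) != 2 || any(lesion_count_range < 1) ||
      lesion_count_range[1] > lesion_count_range[2])
    stop_field("lesion_count_range", "must be a nonempty integer range >= 1")
  if (is.null(lesion_radius_range))
    lesion_radius_range <- pmax(4, round(image_size * c(0.10, 0.20)))
  if (length(lesion_radius_range) != 2 || any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop_field("lesion_radius_range", "must be a nonempty positive range")
  if (!is.numeric(border_softness) || border_softness < 0)
    stop_field("border_softness", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_field("noise_sd", "must be >= 0")
  structure(list(
    n_samples = as.integer(n_samples),
    positive_fraction = positive_fraction,
    image_size = as.integer(image_size),
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_range = lesion_radius_range,
    border_softness = border_softness,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(
    "generator_params: n=%d (%.0f%% positive), %dx%d px, %d-%d lesions r=[%g,%g], softness=%g, noise=%g, seed=%d\n",
    x$n_samples, 100 * x$positive_fraction, x$image_size, x$image_size,
    x$lesion_count_range[1], x$lesion_count_range[2],
    x$lesion_radius_range[1], x$lesion_radius_range[2],
    x$border_softness, x$noise_sd, x$seed))
  invisible(x)
}

# smooth spatial field: blurred white noise rescaled to [-1, 1]
.texture_field <- function(size, sigma) {
  f <- gaussian_blur_mat(matrix(runif(size * size, -1, 1), size, size), sigma)
  r <- max(abs(range(f)), 1e-12)
  f / r
}

# render one lesion as a radially-modulated Gaussian bump whose value is
# exactly 0.5 on the nominal (pre-blur) boundary r(theta)
.lesion_bump <- function(size, cx, cy, r0) {
  amp <- runif(3, 0, 0.12)
  phase <- runif(3, 0, 2 * pi)
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  dx <- xs - cx
  dy <- ys - cy
  d <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  rt <- r0 * (1 + amp[1] * sin(2 * th + phase[1]) +
                amp[2] * sin(3 * th + phase[2]) +
                amp[3] * sin(4 * th + phase[3]))
  exp(-log(2) * (d / pmax(rt, 1))^2)
}

.generate_sample <- function(positive, p) {
  s <- p$image_size
  # skin-toned background with low-frequency texture and per-sample tone jitter
  tone <- c(0.80, 0.58, 0.50) + runif(3, -0.05, 0.05)
  tex <- .texture_field(s, s / 16) * 0.06
  img <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) img[, , ch] <- tone[ch] + tex

  mask <- matrix(0L, s, s)
  if (positive) {
    k <- sample(seq(p$lesion_count_range[1], p$lesion_count_range[2]), 1)
    field <- matrix(0, s, s)
    for (j in seq_len(k)) {
      r0 <- runif(1, p$lesion_radius_range[1], p$lesion_radius_range[2])
      margin <- min(1.25 * r0 + 2, (s - 2) / 2)
      cx <- runif(1, margin, s - margin)
      cy <- runif(1, margin, s - margin)
      field <- pmax(field, .lesion_bump(s, cx, cy, r0))
    }
    # exact label: pre-blur field thresholded at half its peak value (1)
    mask[field > 0.5] <- 1L
    # rendered appearance: blurred field -> diffuse border, reddish tint
    # plus intra-lesion texture
    soft <- gaussian_blur_mat(field, p$border_softness)
    tint <- c(0.10, -0.20, -0.05)
    ltex <- .texture_field(s, s / 24) * 0.05 * soft
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tint[ch] * soft + ltex
  }
  if (p$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, p$noise_sd), dim = dim(img))
  list(image = clip01(img), mask = mask, is_positive = positive)
}

#' Generate a synthetic lesion segmentation dataset
#'
#' Produces `n_samples` image/mask pairs per the supplied
#' [generator_params()]. Exactly `round(positive_fraction * n_samples)`
#' samples are positive (deterministic allocation); positions in the list
#' are shuffled but seeded, so identical parameters and seed reproduce the
#' dataset bit for bit.
#'
#' @param params a [generator_params()] object.
#' @return a list of samples, each a list with `image` (H x W x 3 array in
#'   \[0,1\]), `mask` (H x W integer matrix in \{0,1\}, 1 = lesion) and
#'   `is_positive`.
#' @export
generate_dataset <- function(params) {
  if (!inherits(params, "generator_params"))
    params <- do.call(generator_params, params)
  n <- params$n_samples
  n_pos <- round(params$positive_fraction * n)
  with_seed(params$seed, {
    flags <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    lapply(flags, .generate_sample, p = params)
  })
}

#' Write a dataset to PNG files plus a manifest
#'
#' Images are written as 8-bit RGB PNGs, masks as 8-bit grayscale PNGs with
#' \{0,1\} encoded as \{0,255\}, and a `manifest.csv` lists
#' `image_path,mask_path,is_positive` (paths relative to `directory`).
#'
#' @param samples list of samples as returned by [generate_dataset()].
#' @param directory output directory, created if needed.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(samples, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    img_name <- sprintf("image_%04d.png", i)
    mask_name <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image, file.path(directory, img_name))
    png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask), ncol(s$mask)),
                  file.path(directory, mask_name))
    data.frame(image_path = img_name, mask_path = mask_name,
               is_positive = s$is_positive)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(directory, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Uses `manifest.csv` when present, otherwise pairs `image_*.png` with
#' `mask_*.png` by basename. A missing mask is an error naming the image.
#'
#' @param directory dataset directory.
#' @return a list of samples (see [generate_dataset()]); image intensities
#'   are 8-bit quantized by the PNG round trip, masks are exact.
#' @export
read_dataset <- function(directory) {
  if (!dir.exists(directory))
    stop(sprintf("dataset directory not found: %s", directory), call. = FALSE)
  mpath <- file.path(directory, "manifest.csv")
  if (file.exists(mpath)) {
    manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  } else {
    imgs <- sort(list.files(directory, pattern = "^image_.*\\.png$"))
    if (length(imgs) == 0)
      stop(sprintf("no images found in %s", directory), call. = FALSE)
    manifest <- data.frame(image_path = imgs,
                           mask_path = sub("^image_", "mask_", imgs),
                           is_positive = NA)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    ip <- file.path(directory, manifest$image_path[i])
    mp <- file.path(directory, manifest$mask_path[i])
    if (!file.exists(ip))
      stop(sprintf("missing image file: %s", basename(ip)), call. = FALSE)
    if (!file.exists(mp))
      stop(sprintf("missing mask for image: %s", basename(ip)), call. = FALSE)
    img <- png::readPNG(ip)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    m <- png::readPNG(mp)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    list(image = img, mask = mask, is_positive = any(mask == 1L))
  })
}
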