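# Segmentation and uncertainty-quality metrics. All multi-image variants
# pool pixel/patch counts over images (micro-average); per-image reports
# are obtained by calling the functions on single images.

# core metric computation on flat label vectors (0-based classes)
.metrics_from_vectors <- function(p, g, n_classes, valid_ratio) {
  classes <- seq_len(n_classes) - 1L
  tp <- fp <- fn <- gt_n <- numeric(n_classes)
  for (c in classes) {
    i <- c + 1L
    tp[i] <- sum(p == c & g == c)
    fp[i] <- sum(p == c & g != c)
    fn[i] <- sum(p != c & g == c)
    gt_n[i] <- tp[i] + fn[i]
  }
  denom <- tp + fp + fn
  iou <- ifelse(denom > 0, tp / denom, NA_real_)
  present <- gt_n > 0
  w <- gt_n / sum(gt_n)
  dice_pc <- ifelse(2 * tp + fp + fn > 0,
                    2 * tp / (2 * tp + fp + fn), NA_real_)
  structure(list(
    pixel_accuracy = mean(p == g),
    per_class_iou = iou,
    mean_iou = mean(iou[present]),
    weighted_iou = sum(w[present] * iou[present]),
    dice = dice_pc[2L],                 # lesion (class 1) Dice
    per_class_dice = dice_pc,
    valid_pixel_ratio = valid_ratio,
    n_pixels = length(p)
  ), class = "metric_report")
}

#' Segmentation metrics
#'
#' Computes pixel accuracy, per-class IoU (`TP / (TP + FP + FN)`), mean
#' IoU (unweighted mean over classes present in the ground truth),
#' weighted IoU (weighted by ground-truth pixel share), and the Dice
#' similarity coefficient `2 TP / (2 TP + FP + FN)` for the lesion
#' (foreground) class. When `valid_mask` is given, all metrics are
#' restricted to pixels where it is `TRUE` (used by the
#' uncertainty-thresholded pixel-removal analysis). Passing lists of
#' masks pools pixel counts over images (micro-average).
#'
#' @param pred_mask predicted label matrix in 0..n_classes-1, or a list of
#'   them.
#' @param gt_mask ground-truth label matrix (same shape), or a list.
#' @param valid_mask optional logical matrix (or list) of pixels to score.
#' @param n_classes number of classes (default 2).
#' @return an object of class `metric_report`. Per-class entries that are
#'   undefined (class absent from both prediction and ground truth within
#'   the valid area) are `NA`.
#' @export
segmentation_metrics <- function(pred_mask, gt_mask, valid_mask = NULL,
                                 n_classes = 2L) {
  if (!is.list(pred_mask)) {
    pred_mask <- list(pred_mask); gt_mask <- list(gt_mask)
    if (!is.null(valid_mask)) valid_mask <- list(valid_mask)
  }
  if (length(pred_mask) != length(gt_mask))
    stop_field("gt_mask", "prediction and ground truth counts differ")
  ps <- gs <- vector("list", length(pred_mask))
  total <- 0L
  for (i in seq_along(pred_mask)) {
    p <- pred_mask[[i]]; g <- gt_mask[[i]]
    if (!identical(dim(p), dim(g)))
      stop_field("gt_mask", sprintf("shape mismatch on image %d", i))
    v <- if (is.null(valid_mask)) TRUE else {
      vm <- valid_mask[[i]]
      if (!identical(dim(vm), dim(p)))
        stop_field("valid_mask", sprintf("shape mismatch on image %d", i))
      as.vector(vm)
    }
    total <- total + length(p)
    ps[[i]] <- as.vector(p)[v]
    gs[[i]] <- as.vector(g)[v]
  }
  p <- unlist(ps); g <- unlist(gs)
  if (length(p) == 0)
    stop("no valid pixels to evaluate", call. = FALSE)
  .metrics_from_vectors(p, g, n_classes, length(p) / total)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (%d px, %.0f%% valid): accuracy=%.3f meanIoU=%.3f weightedIoU=%.3f Dice=%.3f\n",
    x$n_pixels, 100 * x$valid_pixel_ratio, x$pixel_accuracy, x$mean_iou,
    x$weighted_iou, x$dice))
  invisible(x)
}

# mean over non-overlapping s x s blocks of matrix M (sides multiples of s)
.block_mean <- function(M, s) {
  H <- nrow(M); W <- ncol(M)
  m1 <- colMeans(array(M, dim = c(s, H / s, W)))        # (H/s) x W
  t(colMeans(array(t(m1), dim = c(s, W / s, H / s))))   # (H/s) x (W/s)
}

#' Patch accuracy / uncertainty tallies
#'
#' Traverses prediction, ground truth and uncertainty map with
#' non-overlapping `patch_size` x `patch_size` windows. A patch is
#' *accurate* iff its pixel accuracy is strictly greater than
#' `accuracy_threshold` (so exactly half correct counts as inaccurate),
#' and *uncertain* iff its mean uncertainty is strictly greater than
#' `uncertainty_threshold` (boundary values count as certain). Returns the
#' four tallies nac (accurate+certain), nau (accurate+uncertain), nic
#' (inaccurate+certain), niu (inaccurate+uncertain).
#'
#' @param pred_mask,gt_mask label matrices.
#' @param uncertainty_map matching matrix, pre-normalized to \[0, 1\].
#' @param patch_size window side (default 2).
#' @param accuracy_threshold patch accuracy cut (default 0.5, strict).
#' @param uncertainty_threshold patch uncertainty cut (strict).
#' @return an object of class `patch_counts` with `nac`, `nau`, `nic`,
#'   `niu`, `n_patches` and the threshold used. Trailing rows/columns not
#'   filling a whole patch are truncated with a warning.
#' @export
patch_counts <- function(pred_mask, gt_mask, uncertainty_map, patch_size = 2L,
                         accuracy_threshold = 0.5, uncertainty_threshold) {
  s <- as.integer(patch_size)
  if (!identical(dim(pred_mask), dim(gt_mask)) ||
      !identical(dim(pred_mask), dim(uncertainty_map)))
    stop_field("gt_mask", "pred, gt and uncertainty shapes must match")
  H <- nrow(pred_mask); W <- ncol(pred_mask)
  if (H %% s != 0 || W %% s != 0) {
    warning(sprintf("truncating %dx%d to a multiple of the %d-pixel patch",
                    H, W, s), call. = FALSE)
    H <- s * (H %/% s); W <- s * (W %/% s)
    pred_mask <- pred_mask[seq_len(H), seq_len(W)]
    gt_mask <- gt_mask[seq_len(H), seq_len(W)]
    uncertainty_map <- uncertainty_map[seq_len(H), seq_len(W)]
  }
  acc <- .block_mean((pred_mask == gt_mask) * 1, s)
  unc <- .block_mean(uncertainty_map, s)
  accurate <- acc > accuracy_threshold
  uncertain <- unc > uncertainty_threshold
  structure(list(nac = sum(accurate & !uncertain),
                 nau = sum(accurate & uncertain),
                 nic = sum(!accurate & !uncertain),
                 niu = sum(!accurate & uncertain),
                 n_patches = length(acc),
                 uncertainty_threshold = uncertainty_threshold),
            class = "patch_counts")
}

#' @export
print.patch_counts <- function(x, ...) {
  cat(sprintf("patch_counts @ t=%g: nac=%d nau=%d nic=%d niu=%d (%d patches)\n",
              x$uncertainty_threshold, x$nac, x$nau, x$nic, x$niu,
              x$n_patches))
  invisible(x)
}

#' Uncertainty-quality metrics from patch tallies
#'
#' The three conditional/combined patch metrics:
#' `p(accurate|certain) = nac / (nac + nic)`,
#' `p(uncertain|inaccurate) = niu / (nic + niu)`,
#' `PAvPU = (nac + niu) / (nac + nau + nic + niu)`.
#'
#' @param counts a [patch_counts()] object (or a list with the four
#'   tallies).
#' @return an object of class `uncertainty_eval`. A zero denominator
#'   yields the documented `NA` sentinel, never an error -- limit
#'   thresholds legitimately empty some categories.
#' @export
uncertainty_eval <- function(counts) {
  n <- counts$nac + counts$nau + counts$nic + counts$niu
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    p_accurate_given_certain = safe(counts$nac, counts$nac + counts$nic),
    p_uncertain_given_inaccurate = safe(counts$niu, counts$nic + counts$niu),
    pavpu = safe(counts$nac + counts$niu, n),
    uncertainty_threshold = counts$uncertainty_threshold %||% NA_real_,
    counts = counts
  ), class = "uncertainty_eval")
}

#' @export
print.uncertainty_eval <- function(x, ...) {
  cat(sprintf(
    "uncertainty_eval @ t=%g: p(acc|cert)=%.3f p(unc|inacc)=%.3f PAvPU=%.3f\n",
    x$uncertainty_threshold, x$p_accurate_given_certain,
    x$p_uncertain_given_inaccurate, x$pavpu))
  invisible(x)
}

# normalize list-or-single arguments for multi-image pooling
.as_image_lists <- function(pred, gt, unc) {
  if (!is.list(pred)) { pred <- list(pred); gt <- list(gt); unc <- list(unc) }
  stopifnot(length(pred) == length(gt), length(pred) == length(unc))
  list(pred = pred, gt = gt, unc = unc)
}

#' Uncertainty-threshold sweep of the patch metrics
#'
#' Evaluates [uncertainty_eval()] at each threshold of a grid with patch
#' counts pooled over all supplied images.
#'
#' @param pred_mask,gt_mask,uncertainty_map matrices or lists of matrices.
#' @param thresholds nonempty numeric grid within \[0, 1\].
#' @param patch_size,accuracy_threshold see [patch_counts()].
#' @param csv optional path; when given the sweep table is also written
#'   as CSV.
#' @return data.frame with one row per threshold: the four tallies and the
#'   three metrics (NA where undefined).
#' @export
threshold_sweep <- function(pred_mask, gt_mask, uncertainty_map, thresholds,
                            patch_size = 2L, accuracy_threshold = 0.5,
                            csv = NULL) {
  if (length(thresholds) == 0)
    stop_field("thresholds", "grid is empty")
  if (any(thresholds < 0 | thresholds > 1))
    stop_field("thresholds", "must lie in [0, 1]")
  L <- .as_image_lists(pred_mask, gt_mask, uncertainty_map)
  rows <- lapply(thresholds, function(t) {
    tot <- list(nac = 0L, nau = 0L, nic = 0L, niu = 0L,
                uncertainty_threshold = t)
    for (i in seq_along(L$pred)) {
      pc <- patch_counts(L$pred[[i]], L$gt[[i]], L$unc[[i]], patch_size,
                         accuracy_threshold, t)
      for (nm in c("nac", "nau", "nic", "niu"))
        tot[[nm]] <- tot[[nm]] + pc[[nm]]
    }
    ev <- uncertainty_eval(tot)
    data.frame(threshold = t, nac = tot$nac, nau = tot$nau, nic = tot$nic,
               niu = tot$niu,
               p_accurate_given_certain = ev$p_accurate_given_certain,
               p_uncertain_given_inaccurate = ev$p_uncertain_given_inaccurate,
               pavpu = ev$pavpu)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Uncertainty-guided pixel-removal analysis
#'
#' For each threshold `t`, pixels with normalized uncertainty `> t` are
#' removed and the segmentation metrics are recomputed on the remaining
#' (valid) pixels, pooling over images. The remaining pixel ratio is
#' `1 - removed pixel ratio`; at `t = 1` nothing is removed and the
#' metrics equal the unmasked report exactly.
#'
#' @param pred_mask,gt_mask,uncertainty_map matrices or lists of matrices;
#'   uncertainty pre-normalized to \[0, 1\].
#' @param thresholds numeric grid in \[0, 1\] (default 0 to 1 by 0.05).
#' @param n_classes number of classes.
#' @param csv optional CSV output path.
#' @return an object of class `removal_curve`: a data.frame with columns
#'   `threshold`, `remaining_pixel_ratio`, `pixel_accuracy`, `mean_iou`,
#'   `weighted_iou`, `dice` (NA sentinels where a threshold removes every
#'   pixel).
#' @export
removal_analysis <- function(pred_mask, gt_mask, uncertainty_map,
                             thresholds = seq(0, 1, by = 0.05),
                             n_classes = 2L, csv = NULL) {
  if (length(thresholds) == 0)
    stop_field("thresholds", "grid is empty")
  L <- .as_image_lists(pred_mask, gt_mask, uncertainty_map)
  rows <- lapply(thresholds, function(t) {
    valid <- lapply(L$unc, function(u) u <= t)
    nvalid <- sum(vapply(valid, sum, numeric(1)))
    ntotal <- sum(vapply(valid, length, numeric(1)))
    if (nvalid == 0) {
      return(data.frame(threshold = t, remaining_pixel_ratio = 0,
                        pixel_accuracy = NA_real_, mean_iou = NA_real_,
                        weighted_iou = NA_real_, dice = NA_real_))
    }
    m <- segmentation_metrics(L$pred, L$gt, valid, n_classes)
    data.frame(threshold = t, remaining_pixel_ratio = nvalid / ntotal,
               pixel_accuracy = m$pixel_accuracy, mean_iou = m$mean_iou,
               weighted_iou = m$weighted_iou, dice = m$dice)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  structure(out, class = c("removal_curve", "data.frame"))
}

#' Threshold achieving a target remaining-pixel ratio
#'
#' Returns the uncertainty threshold at which at least `target_ratio` of
#' the pixels remain: the `target_ratio` lower quantile (type 1, i.e. the
#' smallest observed value with sufficient mass at or below it) of the
#' pooled uncertainty values. A target of 1 returns 1.0, the keep-all
#' threshold.
#'
#' @param uncertainty_map matrix or list of matrices, normalized to
#'   \[0, 1\].
#' @param target_ratio desired fraction of pixels to keep, in (0, 1\].
#' @return a single threshold value.
#' @export
find_threshold_for_remaining_ratio <- function(uncertainty_map, target_ratio) {
  if (!is.numeric(target_ratio) || length(target_ratio) != 1 ||
      target_ratio <= 0 || target_ratio > 1)
    stop_field("target_ratio", "must be in (0, 1]")
  if (target_ratio >= 1) return(1.0)
  u <- unlist(lapply(if (is.list(uncertainty_map)) uncertainty_map
                     else list(uncertainty_map), as.vector))
  unname(quantile(u, probs = target_ratio, type = 1))
}

#' Band of pixels around the ground-truth mask boundary
#'
#' Boundary pixels are those with a 4-neighbour of the opposite class;
#' the band dilates them `width` times with a 3x3 structuring element.
#' Used to test that Monte Carlo uncertainty concentrates at lesion
#' borders.
#'
#' @param mask binary matrix.
#' @param width band half-width in pixels (default 2).
#' @return logical matrix marking the boundary band.
#' @export
boundary_band <- function(mask, width = 2L) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  shift <- function(M, dr, dc) {
    rs <- pmin(pmax(seq_len(H) + dr, 1), H)
    cs <- pmin(pmax(seq_len(W) + dc, 1), W)
    M[rs, cs, drop = FALSE]
  }
  edge <- (m != shift(m, 1, 0)) | (m != shift(m, -1, 0)) |
    (m != shift(m, 0, 1)) | (m != shift(m, 0, -1))
  band <- edge
  for (i in seq_len(width)) {
    band <- band | shift(band, 1, 0) | shift(band, -1, 0) |
      shift(band, 0, 1) | shift(band, 0, -1) |
      shift(band, 1, 1) | shift(band, 1, -1) |
      shift(band, -1, 1) | shift(band, -1, -1)
  }
  band
}
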