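# Independent brute-force oracles. These deliberately use naive pixel /
# patch loops so they share no code path with the package implementations
# they check.

# segmentation metrics by explicit pixel counting
oracle_metrics <- function(pred, gt, valid = NULL, n_classes = 2) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pred), ncol(pred))
  p <- c(); g <- c()
  for (r in seq_len(nrow(pred)))
    for (cc in seq_len(ncol(pred)))
      if (valid[r, cc]) { p <- c(p, pred[r, cc]); g <- c(g, gt[r, cc]) }
  acc <- sum(p == g) / length(p)
  iou <- dice <- rep(NA_real_, n_classes)
  gt_count <- numeric(n_classes)
  for (cl in 0:(n_classes - 1)) {
    tp <- sum(p == cl & g == cl)
    fp <- sum(p == cl & g != cl)
    fn <- sum(p != cl & g == cl)
    gt_count[cl + 1] <- tp + fn
    if (tp + fp + fn > 0) iou[cl + 1] <- tp / (tp + fp + fn)
    if (2 * tp + fp + fn > 0) dice[cl + 1] <- 2 * tp / (2 * tp + fp + fn)
  }
  present <- gt_count > 0
  list(pixel_accuracy = acc,
       per_class_iou = iou,
       mean_iou = mean(iou[present]),
       weighted_iou = sum((gt_count[present] / sum(gt_count)) * iou[present]),
       dice = dice[2])
}

# patch tallies by explicit per-patch enumeration
oracle_patch_counts <- function(pred, gt, unc, t, s = 2, acc_t = 0.5) {
  nac <- nau <- nic <- niu <- 0L
  for (pr in seq_len(nrow(pred) %/% s)) {
    for (pc in seq_len(ncol(pred) %/% s)) {
      rows <- ((pr - 1) * s + 1):(pr * s)
      cols <- ((pc - 1) * s + 1):(pc * s)
      acc <- mean(pred[rows, cols] == gt[rows, cols])
      u <- mean(unc[rows, cols])
      accurate <- acc > acc_t
      uncertain <- u > t
      if (accurate && !uncertain) nac <- nac + 1L
      else if (accurate && uncertain) nau <- nau + 1L
      else if (!accurate && !uncertain) nic <- nic + 1L
      else niu <- niu + 1L
    }
  }
  list(nac = nac, nau = nau, nic = nic, niu = niu)
}

# two-pass per-class population variance, averaged over classes
oracle_variance <- function(samples) {
  d <- dim(samples)
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1]))
    for (cc in seq_len(d[2])) {
      vs <- numeric(d[3])
      for (cl in seq_len(d[3])) {
        xs <- samples[r, cc, cl, ]
        m <- sum(xs) / d[4]
        vs[cl] <- sum((xs - m)^2) / d[4]
      }
      out[r, cc] <- mean(vs)
    }
  out
}

# random label masks / uncertainty maps for property tests
random_mask <- function(h, w, n_classes = 2) {
  matrix(sample(0:(n_classes - 1), h * w, replace = TRUE), h, w)
}
random_unc <- function(h, w) matrix(runif(h * w), h, w)
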