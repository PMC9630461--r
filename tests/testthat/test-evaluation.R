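test_that("segmentation metrics reproduce hand-derived values", {
  gt <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  pred <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  m <- segmentation_metrics(pred, gt)
  expect_equal(m$pixel_accuracy, 3 / 4)
  expect_equal(m$per_class_iou, c(2 / 3, 1 / 2))
  expect_equal(m$mean_iou, 7 / 12)
  expect_equal(m$dice, 2 / 3)
  expect_equal(m$weighted_iou, 0.75 * 2 / 3 + 0.25 * 1 / 2)

  ident <- segmentation_metrics(gt, gt)
  expect_equal(ident$pixel_accuracy, 1)
  expect_equal(ident$mean_iou, 1)
  expect_equal(ident$dice, 1)
})

test_that("metrics match the pixel-counting oracle on random masks", {
  set.seed(21)
  for (i in 1:60) {
    pred <- random_mask(8, 8); gt <- random_mask(8, 8)
    valid <- if (i %% 2 == 0) matrix(runif(64) < 0.8, 8, 8) else NULL
    if (!is.null(valid) && !any(valid)) next
    got <- segmentation_metrics(pred, gt, valid)
    ref <- oracle_metrics(pred, gt, valid)
    for (nm in names(ref)) expect_equal(got[[nm]], ref[[nm]], info = nm)
  }
})

test_that("degenerate class patterns follow the documented conventions", {
  # all-background image, perfectly predicted: lesion skipped, not penalized
  z <- matrix(0L, 4, 4)
  m <- segmentation_metrics(z, z)
  expect_equal(m$mean_iou, 1)
  expect_true(is.na(m$per_class_iou[2]))
  expect_true(is.na(m$dice))

  expect_error(segmentation_metrics(z, matrix(0L, 3, 3)), "shape")
  expect_error(segmentation_metrics(z, z, matrix(FALSE, 4, 4)), "valid")
})

test_that("pooling over images equals metrics on concatenated pixels", {
  set.seed(5)
  preds <- replicate(3, random_mask(6, 6), simplify = FALSE)
  gts <- replicate(3, random_mask(6, 6), simplify = FALSE)
  pooled <- segmentation_metrics(preds, gts)
  flat <- segmentation_metrics(do.call(rbind, preds), do.call(rbind, gts))
  expect_equal(pooled$pixel_accuracy, flat$pixel_accuracy)
  expect_equal(pooled$mean_iou, flat$mean_iou)
})

test_that("patch tallies respect the strict thresholds and conservation", {
  gt <- random_mask(8, 8)
  z <- matrix(0, 8, 8)
  pc <- patch_counts(gt, gt, z, uncertainty_threshold = 0.5)
  expect_equal(pc$nac, 16)
  expect_equal(pc$nau + pc$nic + pc$niu, 0)
  expect_equal(pc$nac + pc$nau + pc$nic + pc$niu, 16)

  # exactly 2 of 4 pixels correct -> accuracy 0.5, NOT > 0.5 -> inaccurate
  gt2 <- matrix(0L, 2, 2)
  pred2 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pc2 <- patch_counts(pred2, gt2, matrix(0, 2, 2), uncertainty_threshold = 0.5)
  expect_equal(pc2$nic, 1)
  expect_equal(pc2$nac, 0)

  # patch uncertainty exactly at the threshold counts as certain
  pc3 <- patch_counts(gt2, gt2, matrix(0.5, 2, 2), uncertainty_threshold = 0.5)
  expect_equal(pc3$nac, 1)

  expect_warning(patch_counts(random_mask(5, 5), random_mask(5, 5),
                              matrix(0, 5, 5), uncertainty_threshold = 0.5),
                 "truncating")
})

test_that("patch counts match exhaustive enumeration across thresholds", {
  set.seed(31)
  thresholds <- seq(0, 1, by = 0.1)
  for (i in 1:20) {
    pred <- random_mask(8, 8); gt <- random_mask(8, 8); unc <- random_unc(8, 8)
    for (t in thresholds) {
      got <- patch_counts(pred, gt, unc, uncertainty_threshold = t)
      ref <- oracle_patch_counts(pred, gt, unc, t)
      expect_equal(got[c("nac", "nau", "nic", "niu")], ref)
    }
  }
})

test_that("uncertainty_eval computes the three quotients with sentinels", {
  ev <- uncertainty_eval(list(nac = 6, nau = 1, nic = 2, niu = 3))
  expect_equal(ev$p_accurate_given_certain, 0.75)
  expect_equal(ev$p_uncertain_given_inaccurate, 0.6)
  expect_equal(ev$pavpu, 0.75)

  ev2 <- uncertainty_eval(list(nac = 4, nau = 2, nic = 0, niu = 0))
  expect_true(is.na(ev2$p_uncertain_given_inaccurate))
  expect_equal(ev2$pavpu, 4 / 6)

  ev3 <- uncertainty_eval(list(nac = 5, nau = 0, nic = 0, niu = 0))
  expect_equal(ev3$p_accurate_given_certain, 1)
  expect_equal(ev3$pavpu, 1)
})

test_that("threshold sweep agrees with direct calls and limit cases", {
  set.seed(41)
  pred <- random_mask(8, 8); gt <- random_mask(8, 8); unc <- random_unc(8, 8)
  sw <- threshold_sweep(pred, gt, unc, thresholds = c(0.3))
  direct <- uncertainty_eval(patch_counts(pred, gt, unc,
                                          uncertainty_threshold = 0.3))
  expect_equal(sw$pavpu, direct$pavpu)
  expect_equal(sw$nac, direct$counts$nac)

  acc_frac <- patch_counts(pred, gt, unc, uncertainty_threshold = 1)$nac / 16
  hi <- threshold_sweep(pred, gt, unc, thresholds = 1)
  expect_equal(hi$nau + hi$niu, 0)
  expect_equal(hi$p_accurate_given_certain, acc_frac)

  lo <- threshold_sweep(pred, gt, unc, thresholds = 0)
  if (min(mcunet:::.block_mean(unc, 2L)) > 0) {
    expect_equal(lo$nac + lo$nic, 0)
    expect_equal(lo$pavpu, 1 - acc_frac)
  }

  expect_error(threshold_sweep(pred, gt, unc, numeric(0)), "thresholds")
  expect_error(threshold_sweep(pred, gt, unc, 1.2), "thresholds")
})

test_that("removal analysis has the identity limit and monotone ratio", {
  set.seed(51)
  pred <- random_mask(10, 10); gt <- random_mask(10, 10)
  unc <- random_unc(10, 10)
  rc <- removal_analysis(pred, gt, unc, thresholds = seq(0, 1, 0.25))
  expect_true(all(diff(rc$remaining_pixel_ratio) >= 0))
  full <- segmentation_metrics(pred, gt)
  last <- nrow(rc)
  expect_equal(rc$remaining_pixel_ratio[last], 1)
  expect_equal(rc$pixel_accuracy[last], full$pixel_accuracy)
  expect_equal(rc$mean_iou[last], full$mean_iou)

  flat <- removal_analysis(pred, gt, matrix(0, 10, 10),
                           thresholds = c(0, 0.5, 1))
  expect_true(all(flat$pixel_accuracy == full$pixel_accuracy))

  # plant all errors under the top-uncertainty decile: removing it fixes them
  gt2 <- matrix(0L, 10, 10)
  pred2 <- gt2
  unc2 <- matrix(runif(100, 0, 0.5), 10, 10)
  bad <- sample(100, 10)
  pred2[bad] <- 1L
  unc2[bad] <- runif(10, 0.9, 1)
  t90 <- find_threshold_for_remaining_ratio(unc2, 0.9)
  rc2 <- removal_analysis(pred2, gt2, unc2, thresholds = c(t90, 1))
  expect_equal(rc2$pixel_accuracy[1], 1)
  expect_lt(rc2$pixel_accuracy[1 + 1], 1)
})

test_that("remaining-ratio threshold finder is a type-1 quantile", {
  expect_equal(find_threshold_for_remaining_ratio(matrix(runif(25), 5), 1), 1)
  u <- matrix((0:99) / 99, 10, 10)
  t90 <- find_threshold_for_remaining_ratio(u, 0.9)
  expect_equal(t90, u[order(u)][90])
  ratio <- mean(u <= t90)
  expect_gte(ratio, 0.90)
  expect_lte(ratio, 0.91)
  set.seed(61)
  uu <- random_unc(8, 8)
  ts <- vapply(c(0.3, 0.6, 0.9), find_threshold_for_remaining_ratio,
               numeric(1), uncertainty_map = uu)
  expect_true(all(diff(ts) >= 0))
  expect_error(find_threshold_for_remaining_ratio(uu, 0), "target_ratio")
})

test_that("boundary band marks the mask border, not far-away pixels", {
  mask <- matrix(0L, 20, 20)
  mask[6:15, 6:15] <- 1L
  band <- boundary_band(mask, width = 2)
  expect_true(band[6, 6])          # corner of the lesion
  expect_true(band[5, 10])         # just outside
  expect_true(band[8, 10])         # 2 px inside the border
  expect_false(band[10, 10])       # deep inside
  expect_false(band[1, 1])         # far corner
})
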