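test_that("mc_sample honours dropout placement and seeding", {
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))

  m_none <- tiny_model(depth = 1, base = 2, placement = "none")
  expect_warning(s0 <- mc_sample(m_none, x, sigma = 5, seed = 1),
                 "no dropout")
  for (i in 2:5) expect_identical(s0[, , , i], s0[, , , 1])
  expect_true(all(variance_map(s0) == 0))

  m <- tiny_model(depth = 1, base = 2, placement = "both")
  s1 <- mc_sample(m, x, sigma = 4, seed = 3)
  s2 <- mc_sample(m, x, sigma = 4, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1[, , , 1], s1[, , , 2]))

  one <- mc_sample(m, x, sigma = 1, seed = 3)
  expect_equal(posterior_mean(one), one[, , , 1])
  expect_true(all(variance_map(one) == 0))

  expect_error(mc_sample(m, x, sigma = 0), "sigma")
})

test_that("posterior mean and variance reproduce hand-computed values", {
  # two samples at one pixel: (0.2, 0.8) and (0.6, 0.4)
  samples <- array(c(0.2, 0.8, 0.6, 0.4), dim = c(1, 1, 2, 2))
  expect_equal(as.vector(posterior_mean(samples)), c(0.4, 0.6))
  # per-class population variance 0.04 each; class-averaged value 0.04
  expect_equal(as.vector(variance_map(samples)), 0.04)

  ident <- array(rep(c(0.3, 0.7), 5), dim = c(1, 1, 2, 5))
  expect_equal(as.vector(posterior_mean(ident)), c(0.3, 0.7))
  expect_true(all(variance_map(ident) == 0))
})

test_that("variance matches the two-pass oracle and the binary bound", {
  set.seed(8)
  for (i in 1:5) {
    raw <- array(runif(6 * 5 * 2 * 7), dim = c(6, 5, 2, 7))
    # normalize to valid softmax pairs
    raw[, , 2, ] <- 1 - raw[, , 1, ]
    expect_lt(max(abs(variance_map(raw) - oracle_variance(raw))), 1e-10)
    expect_true(all(variance_map(raw) <= 0.25))
    m <- posterior_mean(raw)
    expect_true(all(abs(apply(m, c(1, 2), sum) - 1) < 1e-12))
  }
})

test_that("uncertainty normalization follows the min-max convention", {
  expect_equal(as.vector(normalize_uncertainty(matrix(c(0, 2, 4), 1))),
               c(0, 0.5, 1))
  expect_true(all(normalize_uncertainty(matrix(0.3, 4, 4)) == 0))
  set.seed(2)
  u <- normalize_uncertainty(matrix(runif(64, 1, 9), 8, 8))
  expect_equal(min(u), 0)
  expect_equal(max(u), 1)
})

test_that("label prediction is argmax with low-index tie-break", {
  p <- array(c(0.9, 0.5, 0.2, 0.1, 0.5, 0.8), dim = c(1, 3, 2))
  expect_equal(as.vector(predict_labels(p)), c(0L, 0L, 1L))
  set.seed(3)
  probs <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  ref <- matrix(0L, 8, 8)
  for (r in 1:8) for (cc in 1:8)
    ref[r, cc] <- which.max(probs[r, cc, ]) - 1L
  expect_identical(predict_labels(probs), ref)
})

test_that("sampling dispersion shrinks as sigma grows", {
  m <- tiny_model(depth = 1, base = 4, placement = "both")
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  disp <- vapply(c(10, 100), function(sg) {
    means <- vapply(1:6, function(rep)
      mean(variance_map(mc_sample(m, x, sg, seed = 100 * sg + rep))),
      numeric(1))
    sd(means)
  }, numeric(1))
  expect_lt(disp[2], disp[1])
})

test_that("export_maps writes consistent PNGs and a lossless container", {
  m <- tiny_model(depth = 1, base = 2, placement = "both")
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  pred <- mc_predict(m, x, sigma = 4, seed = 5)
  dir <- withr::local_tempdir()
  paths <- export_maps(pred, dir, "case1")
  expect_true(all(file.exists(paths)))

  lab_png <- png::readPNG(paths[["labels"]])
  expect_identical(matrix(as.integer(lab_png > 0.5), 16, 16),
                   matrix(as.integer(pred$label_mask != 0L), 16, 16))
  maps <- readRDS(paths[["maps"]])
  expect_identical(maps$uncertainty_map, pred$uncertainty_map)
  expect_identical(maps$mean_probs, pred$mean_probs)

  # all-zero uncertainty renders an all-black PNG
  pred$uncertainty_map <- matrix(0, 16, 16)
  paths0 <- export_maps(pred, dir, "zero")
  expect_true(all(png::readPNG(paths0[["uncertainty"]]) == 0))
})
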