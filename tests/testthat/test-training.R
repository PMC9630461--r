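test_that("augment produces n seeded, valid copies", {
  s <- tiny_dataset(n = 1, size = 32, pf = 1)[[1]]
  expect_identical(augment_sample(s, 0), list())
  a1 <- augment_sample(s, 4, seed = 9)
  a2 <- augment_sample(s, 4, seed = 9)
  expect_identical(a1, a2)
  for (a in a1) {
    expect_identical(dim(a$image), dim(s$image))
    expect_true(all(a$image >= 0 & a$image <= 1))
    expect_true(all(a$mask %in% c(0L, 1L)))
  }
})

test_that("geometric transforms move image and mask together", {
  s <- tiny_dataset(n = 1, size = 32, pf = 1)[[1]]
  flip <- list(flip_h = TRUE)
  once <- apply_transform(s, flip)
  expect_identical(once$mask, s$mask[, ncol(s$mask):1])
  twice <- apply_transform(once, flip)        # involution
  expect_identical(twice$mask, s$mask)
  expect_equal(twice$image, s$image)

  rot <- apply_transform(s, list(angle = 20, zoom = 1.1))
  expect_identical(dim(rot$mask), dim(s$mask))
  expect_true(all(rot$mask %in% c(0L, 1L)))
})

test_that("photometric transforms leave the mask untouched", {
  s <- tiny_dataset(n = 1, size = 32, pf = 1)[[1]]
  out <- apply_transform(s, list(brightness = 1.2, gamma = 0.8))
  expect_identical(out$mask, s$mask)
  expect_false(identical(out$image, s$image))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("training history and checkpoint rule follow the contract", {
  ds <- tiny_dataset(n = 8, size = 32, pf = 0.75)
  m <- tiny_model(depth = 1, base = 2)
  tc <- train_config(epochs = 3, batch_size = 4, augment_factor = 0,
                     k_folds = 2, seed = 1)
  tr <- train_model(m, ds[1:6], ds[7:8], tc)
  expect_equal(nrow(tr$history), 3)
  expect_equal(tr$best_val_loss, min(tr$history$val_loss))
  expect_equal(tr$history$val_loss[tr$best_epoch], tr$best_val_loss)

  tc1 <- train_config(epochs = 1, batch_size = 4, augment_factor = 0,
                      k_folds = 2, seed = 1)
  tr1 <- train_model(m, ds[1:6], ds[7:8], tc1)
  expect_equal(tr1$best_epoch, 1L)

  expect_error(train_model(m, list(), ds[7:8], tc), "train_samples")
})

test_that("a small model learns a small synthetic task", {
  ds <- tiny_dataset(n = 20, size = 32, pf = 0.8, seed = 5)
  m <- tiny_model(depth = 2, base = 8, placement = "both")
  tc <- train_config(epochs = 6, batch_size = 2, augment_factor = 0,
                     k_folds = 2, seed = 3)
  tr <- train_model(m, ds[1:16], ds[17:20], tc)
  expect_lt(tr$history$train_loss[6], tr$history$train_loss[1])
})

test_that("cross-validation folds partition the dataset reproducibly", {
  ds <- tiny_dataset(n = 10, size = 32, pf = 0.8)
  mc <- model_config(depth = 1, base_channels = 2, dropout_placement = "both")
  tc <- train_config(epochs = 1, batch_size = 4, augment_factor = 1,
                     k_folds = 5, seed = 17)
  cv <- cross_validate(ds, tc, mc)
  tests <- lapply(cv$folds, `[[`, "test_indices")
  expect_true(all(lengths(tests) == 2))
  expect_identical(sort(unlist(tests)), 1:10)

  cv2 <- cross_validate(ds, tc, mc)
  expect_identical(lapply(cv2$folds, `[[`, "test_indices"), tests)

  # aggregate mean is the arithmetic mean of per-fold values
  for (mn in cv$aggregate$metric) {
    per_fold <- vapply(cv$folds, function(f) f$metrics[[mn]], numeric(1))
    expect_equal(cv$aggregate$mean[cv$aggregate$metric == mn], mean(per_fold))
  }

  expect_error(cross_validate(ds, train_config(k_folds = 11), mc), "k_folds")
})
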