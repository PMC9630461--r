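test_that("forward pass is deterministic without dropout, stochastic with", {
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))

  m0 <- tiny_model(depth = 2, base = 8, placement = "none")
  p1 <- unet_forward(m0, x, mode = "mc")$probs
  p2 <- unet_forward(m0, x, mode = "mc")$probs
  expect_identical(p1, p2)

  m1 <- tiny_model(depth = 2, base = 8, placement = "both", rate = 0.5)
  set.seed(1)
  differs <- vapply(1:10, function(i) {
    a <- unet_forward(m1, x, mode = "mc")$probs
    b <- unet_forward(m1, x, mode = "mc")$probs
    any(a != b)
  }, logical(1))
  expect_true(all(differs))
})

test_that("softmax output is a probability map", {
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  for (kind in c("conventional", "separable")) {
    m <- tiny_model(depth = 2, base = 4, kind = kind, placement = "none")
    p <- unet_forward(m, x)$probs
    expect_equal(dim(p), c(16, 16, 2))
    expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
    expect_true(all(p >= 0))
  }
})

test_that("channel schedule doubles down the encoder and halves up the decoder", {
  cfg <- model_config(depth = 3, base_channels = 4, dropout_placement = "none")
  layers <- model_layers(build_model(cfg, seed = 1))
  for (i in 1:3) {
    blk <- layers[layers$name == sprintf("enc%d_conv2", i), ]
    expect_equal(blk$out_ch, 4 * 2^(i - 1))
  }
  ups <- layers[layers$type == "upconv2x2", ]
  expect_true(all(ups$out_ch == ups$in_ch / 2))
  expect_equal(layers[layers$name == "head", "in_ch"], 4)
})

test_that("indivisible input sizes are rejected with the required divisibility", {
  m <- tiny_model(depth = 2, base = 4, placement = "none")
  x <- array(runif(30 * 30 * 3), dim = c(30, 30, 3))
  expect_error(unet_forward(m, x), "divisible by 2\\^depth = 4")
})

test_that("conv_cost matches the printed formulas and the loop-nest oracle", {
  expect_equal(conv_cost(8, 16, 32, 3, "conventional"), 294912)
  expect_equal(conv_cost(8, 16, 32, 3, "separable"), 41984)
  set.seed(4)
  for (i in 1:25) {
    Df <- sample(1:8, 1); M <- sample(1:8, 1)
    N <- sample(1:8, 1); Dk <- sample(1:4, 1)
    for (kind in c("conventional", "separable"))
      expect_identical(conv_cost(Df, M, N, Dk, kind),
                       mcunet:::mac_count_loopnest(Df, M, N, Dk, kind))
    # reduction factor 1/N + 1/Dk^2, checked exactly in integer arithmetic
    expect_identical(conv_cost(Df, M, N, Dk, "separable") * N * Dk^2,
                     conv_cost(Df, M, N, Dk, "conventional") * (N + Dk^2))
  }
  expect_error(conv_cost(0, 1, 1, 1), "Df")
})

test_that("separable models are smaller; dropout placement changes nothing", {
  cfg_c <- model_config(depth = 4, base_channels = 16,
                        conv_kind = "conventional")
  cfg_s <- model_config(depth = 4, base_channels = 16, conv_kind = "separable")
  expect_lt(parameter_count(cfg_s), parameter_count(cfg_c))

  cfg_2x <- model_config(depth = 4, base_channels = 32,
                         conv_kind = "conventional")
  ratio <- parameter_count(cfg_2x) / parameter_count(cfg_c)
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)

  counts <- vapply(c("none", "contracting", "expansive", "both"), function(p)
    parameter_count(model_config(depth = 2, base_channels = 8,
                                 dropout_placement = p)), numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("analytic gradients match finite differences", {
  # biases randomized away from 0 to dodge exact ReLU kinks
  set.seed(11)
  for (kind in c("conventional", "separable")) {
    cfg <- model_config(depth = 2, base_channels = 2, conv_kind = kind,
                        dropout_placement = "none")
    m <- build_model(cfg, seed = 5)
    for (nm in grep("_b$", names(m$params), value = TRUE))
      m$params[[nm]] <- rnorm(length(m$params[[nm]]), 0, 0.1)
    x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
    lab <- matrix(sample(0:1, 64, TRUE), 8, 8)
    fw <- unet_forward(m, x, keep_cache = TRUE)
    lg <- mcunet:::ce_loss_grad(fw$probs, lab)
    gr <- mcunet:::.unet_backward(m, fw$cache, lg$dlogits)
    eps <- 1e-6
    for (nm in names(m$params)) {
      for (j in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
        m2 <- m
        m2$params[[nm]][j] <- m$params[[nm]][j] + eps
        l1 <- mcunet:::ce_loss_grad(unet_forward(m2, x)$probs, lab,
                                    grad = FALSE)$loss
        m2$params[[nm]][j] <- m$params[[nm]][j] - eps
        l0 <- mcunet:::ce_loss_grad(unet_forward(m2, x)$probs, lab,
                                    grad = FALSE)$loss
        fd <- (l1 - l0) / (2 * eps)
        expect_lt(abs(fd - gr[[nm]][j]), 1e-5 + 1e-3 * abs(fd))
      }
    }
  }
})

test_that("checkpoints round-trip with a self-describing sidecar", {
  m <- tiny_model(depth = 1, base = 2)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".yaml")))
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(side$depth, 1)
  expect_equal(side$conv_kind, "conventional")
  back <- load_model(path)
  expect_identical(back$params, m$params)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_identical(unet_forward(back, x)$probs, unet_forward(m, x)$probs)
})
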