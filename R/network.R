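# Forward and backward passes of the UNet. The forward pass is exposed via
# unet_forward(); the backward pass is internal to training. Caches hold
# per-layer inputs, ReLU masks, pooling argmax indices and dropout masks.

.relu <- function(x) { x[x < 0] <- 0; x }

# inverted Bernoulli dropout mask matching x's shape
.dropout_mask <- function(x, rate) {
  array((runif(length(x)) >= rate) / (1 - rate), dim = dim(x))
}

.conv_unit_fwd <- function(h, name, kind, params, cache) {
  if (kind == "conventional") {
    pre <- conv2d_fwd(h, params[[paste0(name, "_w")]],
                      params[[paste0(name, "_b")]], 3L)
    out <- .relu(pre)
    if (!is.null(cache)) cache[[name]] <- list(x = h, act = out > 0)
  } else {
    t1 <- dwconv2d_fwd(h, params[[paste0(name, "_dw")]], 3L)
    pre <- conv2d_fwd(t1, params[[paste0(name, "_pw")]],
                      params[[paste0(name, "_b")]], 1L)
    out <- .relu(pre)
    if (!is.null(cache)) cache[[name]] <- list(x = h, t = t1, act = out > 0)
  }
  out
}

.conv_unit_bwd <- function(g, name, kind, params, cache, grads) {
  cc <- cache[[name]]
  g <- g * cc$act
  if (kind == "conventional") {
    r <- conv2d_bwd(cc$x, params[[paste0(name, "_w")]], g, 3L)
    grads[[paste0(name, "_w")]] <- grads[[paste0(name, "_w")]] + r$dw
    grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] + as.numeric(r$db)
    r$dx
  } else {
    r2 <- conv2d_bwd(cc$t, params[[paste0(name, "_pw")]], g, 1L)
    grads[[paste0(name, "_pw")]] <- grads[[paste0(name, "_pw")]] + r2$dw
    grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] + as.numeric(r2$db)
    r1 <- dwconv2d_bwd(cc$x, params[[paste0(name, "_dw")]], r2$dx, 3L)
    grads[[paste0(name, "_dw")]] <- grads[[paste0(name, "_dw")]] + r1$dw
    r1$dx
  }
}

#' Forward pass of the UNet
#'
#' Runs the network on one image. In mode `"off"` dropout is disabled and
#' the pass is deterministic; in `"mc"` (Monte Carlo sampling) and
#' `"train"` the configured dropout layers are active and each call draws
#' fresh Bernoulli masks from the R RNG.
#'
#' @param model a [build_model()] result.
#' @param x H x W x C image array; H and W must be divisible by
#'   `2^depth`.
#' @param mode `"off"`, `"mc"` or `"train"`.
#' @param keep_cache keep intermediate activations (needed for the
#'   internal backward pass).
#' @return list with `probs` (H x W x n_classes softmax output, channels
#'   summing to 1 at every pixel) and, if requested, `cache`.
#' @export
unet_forward <- function(model, x, mode = c("off", "mc", "train"),
                         keep_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$config
  d <- cfg$depth
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1L))
  hw <- dim(x)[1:2]
  if (any(hw %% 2^d != 0))
    stop(sprintf("image sides (%d x %d) must be divisible by 2^depth = %d",
                 hw[1], hw[2], 2^d), call. = FALSE)
  if (dim(x)[3] != model$input_channels)
    stop(sprintf("expected %d input channels, got %d",
                 model$input_channels, dim(x)[3]), call. = FALSE)
  active <- mode != "off" && cfg$dropout_placement != "none" &&
    cfg$dropout_rate > 0
  drop_c <- active && cfg$dropout_placement %in% c("contracting", "both")
  drop_e <- active && cfg$dropout_placement %in% c("expansive", "both")
  params <- model$params
  kind <- cfg$conv_kind
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  skips <- vector("list", d)

  h <- x
  for (i in seq_len(d)) {
    h <- .conv_unit_fwd(h, sprintf("enc%d_conv1", i), kind, params, cache)
    h <- .conv_unit_fwd(h, sprintf("enc%d_conv2", i), kind, params, cache)
    skips[[i]] <- h
    pl <- maxpool2_fwd(h)
    if (keep_cache)
      cache[[sprintf("enc%d_pool", i)]] <-
        list(idx = pl$idx, H = dim(h)[1], W = dim(h)[2])
    h <- pl$y
    if (drop_c) {
      m <- .dropout_mask(h, cfg$dropout_rate)
      h <- h * m
      if (keep_cache) cache[[sprintf("enc%d_drop", i)]] <- m
    }
  }
  h <- .conv_unit_fwd(h, "bottleneck_conv1", kind, params, cache)
  h <- .conv_unit_fwd(h, "bottleneck_conv2", kind, params, cache)
  for (i in rev(seq_len(d))) {
    if (keep_cache) cache[[sprintf("dec%d_up_x", i)]] <- h
    h <- upconv2_fwd(h, params[[sprintf("dec%d_up_w", i)]],
                     params[[sprintf("dec%d_up_b", i)]])
    if (drop_e) {
      m <- .dropout_mask(h, cfg$dropout_rate)
      h <- h * m
      if (keep_cache) cache[[sprintf("dec%d_drop", i)]] <- m
    }
    sk <- skips[[i]]
    h <- array(c(h, sk), dim = c(dim(h)[1:2], dim(h)[3] + dim(sk)[3]))
    h <- .conv_unit_fwd(h, sprintf("dec%d_conv1", i), kind, params, cache)
    h <- .conv_unit_fwd(h, sprintf("dec%d_conv2", i), kind, params, cache)
  }
  if (keep_cache) cache$head_x <- h
  logits <- conv2d_fwd(h, params$head_w, params$head_b, 1L)
  list(probs = softmax_hwc(logits), cache = cache)
}

# Backward pass: dlogits -> gradients for every parameter.
# `cache` must come from unet_forward(..., keep_cache = TRUE) with the same
# dropout masks. Returns a named list of gradient arrays.
.unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  d <- cfg$depth
  b <- cfg$base_channels
  kind <- cfg$conv_kind
  params <- model$params
  grads <- new.env(parent = emptyenv())
  for (nm in names(params)) grads[[nm]] <- array(0, dim = dim(params[[nm]]) %||% length(params[[nm]]))
  for (nm in names(params))
    if (is.null(dim(params[[nm]]))) grads[[nm]] <- numeric(length(params[[nm]]))

  r <- conv2d_bwd(cache$head_x, params$head_w, dlogits, 1L)
  grads$head_w <- grads$head_w + r$dw
  grads$head_b <- grads$head_b + as.numeric(r$db)
  g <- r$dx

  dskip <- vector("list", d)
  for (i in seq_len(d)) {           # decoder blocks in reverse execution order
    g <- .conv_unit_bwd(g, sprintf("dec%d_conv2", i), kind, params, cache, grads)
    g <- .conv_unit_bwd(g, sprintf("dec%d_conv1", i), kind, params, cache, grads)
    ci <- b * 2^(i - 1)
    gup <- g[, , seq_len(ci), drop = FALSE]
    dskip[[i]] <- g[, , ci + seq_len(ci), drop = FALSE]
    m <- cache[[sprintf("dec%d_drop", i)]]
    if (!is.null(m)) gup <- gup * m
    r <- upconv2_bwd(cache[[sprintf("dec%d_up_x", i)]],
                     params[[sprintf("dec%d_up_w", i)]], gup)
    grads[[sprintf("dec%d_up_w", i)]] <-
      grads[[sprintf("dec%d_up_w", i)]] + r$dw
    grads[[sprintf("dec%d_up_b", i)]] <-
      grads[[sprintf("dec%d_up_b", i)]] + as.numeric(r$db)
    g <- r$dx
  }
  g <- .conv_unit_bwd(g, "bottleneck_conv2", kind, params, cache, grads)
  g <- .conv_unit_bwd(g, "bottleneck_conv1", kind, params, cache, grads)
  for (i in rev(seq_len(d))) {      # encoder blocks in reverse execution order
    m <- cache[[sprintf("enc%d_drop", i)]]
    if (!is.null(m)) g <- g * m
    pl <- cache[[sprintf("enc%d_pool", i)]]
    g <- maxpool2_bwd(g, pl$idx, pl$H, pl$W)
    g <- g + dskip[[i]]
    g <- .conv_unit_bwd(g, sprintf("enc%d_conv2", i), kind, params, cache, grads)
    g <- .conv_unit_bwd(g, sprintf("enc%d_conv1", i), kind, params, cache, grads)
  }
  as.list(grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
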