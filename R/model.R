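#' UNet architecture configuration
#'
#' Describes the encoder--decoder segmentation network. The contracting
#' path has `depth` blocks of two 3x3 same-padding convolutions + ReLU
#' followed by 2x2 stride-2 max pooling, with the feature channel count
#' doubling at each downsampling; a two-convolution bottleneck sits at the
#' bottom; each expansive block applies a 2x2 up-convolution that halves
#' the channels, concatenates the matching contracting feature map, and
#' applies two 3x3 convolutions + ReLU; a 1x1 convolution + softmax head
#' produces per-pixel class probabilities.
#'
#' Monte Carlo dropout layers (Bernoulli, rate `dropout_rate`) are placed
#' immediately after the max pooling of each contracting block and/or
#' immediately after each up-convolution (before concatenation), per
#' `dropout_placement`. They stay active at inference when sampling.
#'
#' @param depth number of contracting blocks (>= 1).
#' @param base_channels feature channels of the first block (>= 1).
#' @param n_classes output classes (>= 2; default 2, background/lesion).
#' @param conv_kind `"conventional"` 3x3 convolutions, or `"separable"`
#'   (depthwise 3x3 then pointwise 1x1) in both paths; up-convolutions and
#'   the 1x1 head stay conventional.
#' @param dropout_placement one of `"none"`, `"contracting"`,
#'   `"expansive"`, `"both"`.
#' @param dropout_rate dropout probability in \[0, 1).
#' @return an object of class `model_config`.
#' @export
model_config <- function(depth = 4,
                         base_channels = 16,
                         n_classes = 2,
                         conv_kind = c("conventional", "separable"),
                         dropout_placement = c("none", "contracting",
                                               "expansive", "both"),
                         dropout_rate = 0.5) {
  conv_kind <- match.arg(conv_kind)
  dropout_placement <- match.arg(dropout_placement)
  if (!is.numeric(depth) || depth < 1) stop_field("depth", "must be >= 1")
  if (!is.numeric(base_channels) || base_channels < 1)
    stop_field("base_channels", "must be >= 1")
  if (!is.numeric(n_classes) || n_classes < 2)
    stop_field("n_classes", "must be >= 2")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop_field("dropout_rate", "must be in [0, 1)")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 conv_kind = conv_kind,
                 dropout_placement = dropout_placement,
                 dropout_rate = dropout_rate),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "model_config: depth=%d base=%d classes=%d conv=%s dropout=%s(%.2f)\n",
    x$depth, x$base_channels, x$n_classes, x$conv_kind,
    x$dropout_placement, x$dropout_rate))
  invisible(x)
}

# He-normal initialized weight array
.he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# register one convolution unit (conventional or separable) in a model
# under construction; returns updated params/layers
.add_conv_unit <- function(st, name, cin, cout, kind) {
  if (kind == "conventional") {
    st$params[[paste0(name, "_w")]] <- .he_init(c(3, 3, cin, cout), 9 * cin)
    st$params[[paste0(name, "_b")]] <- numeric(cout)
    st$layers <- rbind(st$layers, data.frame(
      name = name, type = "conv3x3", kernel = 3L, in_ch = cin, out_ch = cout))
  } else {
    st$params[[paste0(name, "_dw")]] <- .he_init(c(3, 3, cin), 9)
    st$params[[paste0(name, "_pw")]] <- .he_init(c(1, 1, cin, cout), cin)
    st$params[[paste0(name, "_b")]] <- numeric(cout)
    st$layers <- rbind(st$layers, data.frame(
      name = name, type = "separable3x3", kernel = 3L, in_ch = cin,
      out_ch = cout))
  }
  st
}

#' Build a UNet segmentation model
#'
#' Instantiates the network described by a [model_config()] with He-normal
#' initialized weights. The forward pass maps an H x W x 3 image (H and W
#' divisible by `2^depth`) to an H x W x n_classes softmax probability
#' array; same-padding convolutions keep the output at full image size so
#' no cropping of skip connections is needed.
#'
#' @param config a [model_config()].
#' @param input_channels image channels (default 3, RGB).
#' @param seed optional seed for reproducible initialization.
#' @return an object of class `unet_model` with elements `config`,
#'   `input_channels`, `params` (named list of weight arrays) and `layers`
#'   (introspection table, see [model_layers()]).
#' @export
build_model <- function(config, input_channels = 3L, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    st <- list(params = list(), layers = NULL)
    d <- config$depth
    b <- config$base_channels
    cin <- input_channels
    for (i in seq_len(d)) {
      ci <- b * 2^(i - 1)
      st <- .add_conv_unit(st, sprintf("enc%d_conv1", i), cin, ci,
                           config$conv_kind)
      st <- .add_conv_unit(st, sprintf("enc%d_conv2", i), ci, ci,
                           config$conv_kind)
      st$layers <- rbind(st$layers, data.frame(
        name = sprintf("enc%d_pool", i), type = "maxpool2x2", kernel = 2L,
        in_ch = ci, out_ch = ci))
      cin <- ci
    }
    cb <- b * 2^d
    st <- .add_conv_unit(st, "bottleneck_conv1", cin, cb, config$conv_kind)
    st <- .add_conv_unit(st, "bottleneck_conv2", cb, cb, config$conv_kind)
    ch <- cb
    for (i in rev(seq_len(d))) {
      ci <- b * 2^(i - 1)
      st$params[[sprintf("dec%d_up_w", i)]] <- .he_init(c(2, 2, ch, ci), 4 * ch)
      st$params[[sprintf("dec%d_up_b", i)]] <- numeric(ci)
      st$layers <- rbind(st$layers, data.frame(
        name = sprintf("dec%d_up", i), type = "upconv2x2", kernel = 2L,
        in_ch = ch, out_ch = ci))
      st <- .add_conv_unit(st, sprintf("dec%d_conv1", i), 2 * ci, ci,
                           config$conv_kind)
      st <- .add_conv_unit(st, sprintf("dec%d_conv2", i), ci, ci,
                           config$conv_kind)
      ch <- ci
    }
    st$params$head_w <- .he_init(c(1, 1, b, config$n_classes), b)
    st$params$head_b <- numeric(config$n_classes)
    st$layers <- rbind(st$layers, data.frame(
      name = "head", type = "conv1x1", kernel = 1L, in_ch = b,
      out_ch = config$n_classes))
    structure(list(config = config,
                   input_channels = as.integer(input_channels),
                   params = st$params, layers = st$layers),
              class = "unet_model")
  })
}

#' Layer table of a built model
#'
#' @param model a [build_model()] result.
#' @return a data.frame with one row per layer: `name`, `type`, `kernel`,
#'   `in_ch`, `out_ch`, in execution order. Useful for asserting the
#'   channel-doubling / halving schedule.
#' @export
model_layers <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  model$layers
}

#' @export
print.unet_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d layers, %s trainable parameters\n",
              nrow(x$layers), format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Multiply-accumulate cost of a convolution layer
#'
#' Closed-form cost of one convolution over a `Df` x `Df` feature map with
#' `M` input channels, `N` output channels and a `Dk` x `Dk` kernel:
#' conventional `Df^2 * M * N * Dk^2`; depthwise-separable
#' `Df^2 * M * Dk^2 + Df^2 * M * N` (depthwise plus pointwise pass), i.e.
#' cheaper by the factor `1/N + 1/Dk^2`.
#'
#' @param Df spatial width/height of the input feature map.
#' @param M input channels.
#' @param N output channels.
#' @param Dk kernel spatial dimension.
#' @param kind `"conventional"` or `"separable"`.
#' @return exact multiply-accumulate count (numeric, integer-valued).
#' @export
conv_cost <- function(Df, M, N, Dk, kind = c("conventional", "separable")) {
  kind <- match.arg(kind)
  for (nm in c("Df", "M", "N", "Dk")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop_field(nm, "must be a positive integer")
  }
  Df <- as.numeric(Df); M <- as.numeric(M)
  N <- as.numeric(N); Dk <- as.numeric(Dk)
  if (kind == "conventional") Df * Df * M * N * Dk * Dk
  else Df * Df * M * Dk * Dk + Df * Df * M * N
}

#' Count trainable parameters of a model configuration
#'
#' @param config a [model_config()] or an already built `unet_model`.
#' @param input_channels image channels (ignored for a built model).
#' @return total number of trainable scalars. Dropout adds none, so the
#'   count is identical across dropout placements.
#' @export
parameter_count <- function(config, input_channels = 3L) {
  model <- if (inherits(config, "unet_model")) config
           else build_model(config, input_channels, seed = 0L)
  sum(vapply(model$params, length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file; a YAML sidecar (`<path>.yaml`) records
#' the full architecture configuration so checkpoints are self-describing.
#'
#' @param model a `unet_model`.
#' @param path checkpoint file path.
#' @return `save_model`: `path`, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  side <- c(unclass(model$config),
            list(input_channels = model$input_channels,
                 package_version = as.character(utils::packageVersion("mcunet"))))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}
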