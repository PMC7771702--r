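# The stage-two fully convolutional network: an encoder of three 3x3
# convolutions plus three bottleneck-residual blocks (3/4/6 layers,
# channels 32 -> 128 -> 256 -> 512, each block halving the spatial size),
# three transposed-convolution decoder branches restoring full resolution
# with 2 channels each, channel concatenation, and a two-layer head whose
# last convolution carries neither batch norm nor activation (the output
# regresses a Gaussian surface, not a probability).

#' FCN architecture configuration
#'
#' @param net_size Input side length `n` (must be divisible by 16; the
#'   encoder halves the size four times).
#' @param width_multiplier Scales every channel count; 1 is the full
#'   architecture, 1/4 the tiny test preset.
#' @param conv1_layers,conv1_out_channels Stem: number of 3x3 convolutions
#'   and their width (first one has stride 2).
#' @param bottleneck_layer_counts,bottleneck_out_channels Per-block
#'   bottleneck counts and output widths.
#' @param bottleneck_reduction Channel compression inside a bottleneck
#'   (internal width = output width / reduction).
#' @param out_channels Output channels (2: bregma and lambda).
#' @return An object of class `fcn_config`.
#' @export
fcn_config <- function(net_size = 256L, width_multiplier = 1,
                       conv1_layers = 3L, conv1_out_channels = 32L,
                       bottleneck_layer_counts = c(3L, 4L, 6L),
                       bottleneck_out_channels = c(128L, 256L, 512L),
                       bottleneck_reduction = 4L, out_channels = 2L) {
  if (net_size %% 16L != 0L)
    stop_skullmark("invalid_config", "net_size must be divisible by 16")
  ch <- function(x) pmax(2L, as.integer(round(x * width_multiplier)))
  structure(list(
    net_size = as.integer(net_size),
    width_multiplier = width_multiplier,
    conv1_layers = as.integer(conv1_layers),
    conv1_out_channels = ch(conv1_out_channels),
    bottleneck_layer_counts = as.integer(bottleneck_layer_counts),
    bottleneck_out_channels = ch(bottleneck_out_channels),
    bottleneck_reduction = as.integer(bottleneck_reduction),
    conv2_mid_channels = max(4L, ch(16L)),
    out_channels = as.integer(out_channels)
  ), class = "fcn_config")
}

#' Bottleneck residual unit specification
#'
#' @param n_in,n_out Input and output channel counts.
#' @param stride 1 or 2 (2 halves the spatial size).
#' @param reduction Internal channel compression factor (default 4).
#' @return An object of class `bottleneck_spec` with the derived
#'   `internal_channels` and whether the shortcut is an identity.
#' @export
bottleneck_spec <- function(n_in, n_out, stride = 1L, reduction = 4L) {
  internal <- max(1L, as.integer(round(n_out / reduction)))
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 stride = as.integer(stride), internal_channels = internal,
                 identity_shortcut = (n_in == n_out && stride == 1L)),
            class = "bottleneck_spec")
}

# Append one bottleneck unit to graph g:
# 1x1 conv (-> internal, BN, ReLU), 3x3 conv (stride, BN, ReLU),
# 1x1 conv (-> n_out, BN), plus identity or projected shortcut,
# then ReLU after the residual add.
add_bottleneck <- function(g, inp, spec) {
  f <- nn_conv_bn_relu(g, inp, spec$internal_channels, k = 1L)
  f <- nn_conv_bn_relu(g, f, spec$internal_channels, k = 3L,
                       stride = spec$stride)
  f <- nn_conv_bn_relu(g, f, spec$n_out, k = 1L, act = FALSE)
  sc <- if (spec$identity_shortcut) inp
        else nn_conv_bn_relu(g, inp, spec$n_out, k = 1L,
                             stride = spec$stride, act = FALSE)
  nn_add(g, "relu", nn_add(g, "add", c(f, sc)))
}

# Decoder branch: `steps` stride-2 transposed convolutions halving the
# channel count each step, then a 1x1 convolution to `out_ch` (BN + ReLU).
add_deconv_branch <- function(g, inp, in_ch, steps, out_ch) {
  x <- inp; c_now <- in_ch
  for (s in seq_len(steps)) {
    c_now <- max(2L, c_now %/% 2L)
    x <- nn_deconv_bn_relu(g, x, c_now)
  }
  nn_conv_bn_relu(g, x, out_ch, k = 1L)
}

#' Build the heatmap-regression FCN
#'
#' Constructs the full graph with seeded He-initialized weights.  The
#' spatial trace is `n -> n/2` (stem) `-> n/4 -> n/8 -> n/16` (bottleneck
#' blocks); the decoder branches return each block output to `n x n x 2`,
#' their concatenation is `n x n x 6`, and the head maps it to `n x n x 2`.
#'
#' @param config An [fcn_config()].
#' @param seed Weight-initialization seed.
#' @return An object of class `skullmark_fcn` (untrained).
#' @export
build_fcn <- function(config = fcn_config(), seed = 1L) {
  stopifnot(inherits(config, "fcn_config"))
  g <- nn_graph()
  blocks <- list()
  inp <- nn_add(g, "input", shape = c(config$net_size, config$net_size, 3L))
  x <- nn_conv_bn_relu(g, inp, config$conv1_out_channels, k = 3L, stride = 2L)
  for (i in seq_len(config$conv1_layers - 1L))
    x <- nn_conv_bn_relu(g, x, config$conv1_out_channels, k = 3L)
  blocks$conv1 <- x

  chs <- c(config$conv1_out_channels, config$bottleneck_out_channels)
  for (b in seq_along(config$bottleneck_layer_counts)) {
    for (j in seq_len(config$bottleneck_layer_counts[b])) {
      spec <- bottleneck_spec(
        n_in = if (j == 1L) chs[b] else chs[b + 1L],
        n_out = chs[b + 1L],
        stride = if (j == 1L) 2L else 1L,
        reduction = config$bottleneck_reduction)
      x <- add_bottleneck(g, x, spec)
    }
    blocks[[paste0("bottleneck", b)]] <- x
  }

  branches <- integer(3)
  for (b in 1:3)
    branches[b] <- add_deconv_branch(g, blocks[[paste0("bottleneck", b)]],
                                     config$bottleneck_out_channels[b],
                                     steps = b + 1L,
                                     out_ch = config$out_channels)
  blocks$branches <- branches
  cat_id <- nn_add(g, "concat", branches)
  h <- nn_conv_bn_relu(g, cat_id, config$conv2_mid_channels, k = 3L)
  out <- nn_add(g, "conv", h, k = 3L, stride = 1L, pad = 1L,
                out_ch = config$out_channels, init_scale = 0.1)
  blocks$out <- out

  ini <- with_seed(seed, nn_init(g, NULL))
  structure(list(net = list(nodes = ini$nodes, out = out),
                 shapes = ini$shapes, blocks = blocks, config = config,
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "skullmark_fcn")
}

#' @export
print.skullmark_fcn <- function(x, ...) {
  cat(sprintf("<skullmark_fcn> n=%d width=%.3g  %s  %d parameters\n",
              x$config$net_size, x$config$width_multiplier,
              if (x$trained) "trained" else "untrained",
              nn_n_params(x$net)))
  invisible(x)
}

#' Run one bottleneck unit in isolation
#'
#' Functional form of the residual unit used to test its wiring: builds a
#' one-unit graph for `spec`, seeds the weights, and runs a forward pass.
#'
#' @param x Input `(H, W, C, N)` array with `C == spec$n_in`.
#' @param spec A [bottleneck_spec()].
#' @param seed Weight seed.
#' @param zero_weights If `TRUE`, all convolution weights are set to zero
#'   (the zero-residual limit: the unit reduces to `relu(shortcut(x))`).
#' @return The output array.
#' @export
bottleneck_forward <- function(x, spec, seed = 1L, zero_weights = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[3L] != spec$n_in)
    stop_skullmark("shape", sprintf("input has %d channels, spec expects %d",
                                    if (length(d) == 4L) d[3L] else -1L,
                                    spec$n_in))
  g <- nn_graph()
  inp <- nn_add(g, "input", shape = d[1:3])
  out <- add_bottleneck(g, inp, spec)
  ini <- with_seed(seed, nn_init(g, NULL))
  net <- list(nodes = ini$nodes, out = out)
  if (zero_weights)
    for (i in seq_along(net$nodes))
      if (!is.null(net$nodes[[i]]$par$W))
        net$nodes[[i]]$par$W[] <- 0
  nn_forward(net, x, training = FALSE)$out
}

#' FCN training configuration
#'
#' @param epochs Training epochs (study value 50; the tiny protocol uses
#'   30).
#' @param batch_size Minibatch size (8).
#' @param learning_rate Adam learning rate (0.001, the optimizer default).
#' @param seed Seed governing weight init, shuffling and any augmentation.
#' @return An object of class `fcn_train_config`.
#' @export
fcn_train_config <- function(epochs = 50L, batch_size = 8L,
                             learning_rate = 0.001, seed = 1L) {
  if (learning_rate <= 0 || epochs < 1)
    stop_skullmark("invalid_config", "learning_rate > 0 and epochs >= 1 required")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "fcn_train_config")
}

normalize_net_image <- function(x) {
  if (max(x) > 1.5) x / 255 else x
}

#' Train the FCN on (net image, heatmap label) pairs
#'
#' Minimizes the mean squared error over all pixels and both channels with
#' Adam.  Validation loss is computed each epoch on un-augmented pairs in
#' inference mode, and the best-validation weights are kept.
#'
#' @param train_pairs List with `x` (`n x n x 3 x N` images, `[0,1]` or
#'   `[0,255]`) and `y` (`n x n x 2 x N` labels).
#' @param val_pairs Same structure (may be `NULL`).
#' @param train_config An [fcn_train_config()].
#' @param config An [fcn_config()]; defaults to a config matching the
#'   training image size with width 1/4 when `n <= 64` else full width.
#' @return A trained `skullmark_fcn` with `$history` (per-epoch train and
#'   validation loss) and `$best_epoch`.
#' @export
train_fcn <- function(train_pairs, val_pairs = NULL,
                      train_config = fcn_train_config(),
                      config = NULL) {
  dx <- dim(train_pairs$x); dy <- dim(train_pairs$y)
  if (is.null(dx) || length(dx) != 4L)
    stop_skullmark("shape", "train_pairs$x must be (n, n, 3, N)")
  if (!identical(dx[c(1L, 2L, 4L)], dy[c(1L, 2L, 4L)]) || dy[3L] != 2L)
    stop_skullmark("shape", "labels must be (n, n, 2, N) matching the images")
  if (is.null(config))
    config <- fcn_config(net_size = dx[1L],
                         width_multiplier = if (dx[1L] <= 64L) 0.25 else 1)
  if (config$net_size != dx[1L])
    stop_skullmark("shape", "config net_size does not match the images")
  model <- build_fcn(config, seed = train_config$seed)
  x <- normalize_net_image(train_pairs$x)
  vx <- NULL; vy <- NULL
  if (!is.null(val_pairs)) {
    vx <- normalize_net_image(val_pairs$x)
    vy <- val_pairs$y
  }
  fit <- with_seed(derive_seed(train_config$seed, 1L),
    nn_fit(model$net, x, train_pairs$y,
           epochs = train_config$epochs,
           batch_size = train_config$batch_size,
           lr = train_config$learning_rate,
           val_x = vx, val_y = vy))
  model$net <- if (!is.null(val_pairs)) fit$best_net else fit$net
  model$final_net <- NULL
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$train_config <- train_config
  model$trained <- TRUE
  model
}

#' Predict the 2-channel heatmap for one network input
#'
#' @param model A `skullmark_fcn`.
#' @param net_image `n x n x 3` array.
#' @return `n x n x 2` array.
#' @export
predict_heatmaps <- function(model, net_image) {
  stopifnot(inherits(model, "skullmark_fcn"))
  d <- dim(net_image)
  if (length(d) != 3L || d[1L] != model$config$net_size ||
      d[2L] != model$config$net_size)
    stop_skullmark("shape", "net_image does not match the model's net_size")
  x <- array(normalize_net_image(net_image), c(d, 1L))
  nn_forward(model$net, x, training = FALSE)$out[, , , 1L]
}

#' Predict landmark coordinates in the crop frame
#'
#' Runs the FCN, decodes the per-channel argmax and maps the coordinates
#' to the crop frame.  The default decodes at net resolution and scales by
#' `crop_size / net_size`; `decode = "upscale_argmax"` first bilinearly
#' resizes the heatmaps to the crop size and then takes the argmax
#' (equivalent up to interpolation smoothing).
#'
#' @param model A trained `skullmark_fcn`.
#' @param net_image `n x n x 3` network input.
#' @param window The [crop_window()] the input was extracted with.
#' @param decode `"net_argmax"` or `"upscale_argmax"`.
#' @return A crop-frame [landmark_set()] with the window attached as
#'   attribute `window`.
#' @export
predict_landmarks <- function(model, net_image, window,
                              decode = c("net_argmax", "upscale_argmax")) {
  decode <- match.arg(decode)
  if (!isTRUE(model$trained))
    stop_skullmark("state", "model has not been trained")
  stopifnot(inherits(window, "crop_window"))
  hm <- predict_heatmaps(model, net_image)
  if (decode == "net_argmax") {
    lm_net <- decode_heatmap(hm, frame = "net")
    lm <- list(bregma = lm_net$bregma * window$scale,
               lambda = lm_net$lambda * window$scale, frame = "crop")
  } else {
    up <- array(0, c(window$crop_size, window$crop_size, 2L))
    for (ch in 1:2)
      up[, , ch] <- resize_matrix(hm[, , ch],
                                  c(window$crop_size, window$crop_size),
                                  "bilinear")
    lm <- unclass(decode_heatmap(up, frame = "crop"))
  }
  structure(lm, class = "landmark_set", window = window)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the weights, the config echo, the seed
#' and the loss history.
#'
#' @param model A `skullmark_fcn` or `roi_regressor`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
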