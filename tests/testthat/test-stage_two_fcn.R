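test_that("the architecture schedule matches the design at full width", {
  cfg <- fcn_config(net_size = 64L, width_multiplier = 1)
  expect_equal(cfg$conv1_out_channels, 32L)
  expect_equal(cfg$bottleneck_out_channels, c(128L, 256L, 512L))
  expect_equal(cfg$bottleneck_layer_counts, c(3L, 4L, 6L))
  model <- build_fcn(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fw <- skullmark:::nn_forward(model$net, x, training = FALSE)
  dims <- lapply(fw$outs, dim)
  # spatial trace n -> n/2 -> n/4 -> n/8 -> n/16, channels 3-32-128-256-512
  expect_equal(dims[[model$blocks$conv1]], c(32, 32, 32, 1))
  expect_equal(dims[[model$blocks$bottleneck1]], c(16, 16, 128, 1))
  expect_equal(dims[[model$blocks$bottleneck2]], c(8, 8, 256, 1))
  expect_equal(dims[[model$blocks$bottleneck3]], c(4, 4, 512, 1))
  # each decoder branch restores n x n x 2; concat is n x n x 6
  for (b in model$blocks$branches)
    expect_equal(dims[[b]], c(64, 64, 2, 1))
  expect_equal(dim(fw$out), c(64, 64, 2, 1))
})

test_that("shape contract holds for n in {64, 128, 256}", {
  for (n in c(64L, 128L, 256L)) {
    cfg <- fcn_config(net_size = n, width_multiplier = 0.25)
    model <- build_fcn(cfg, seed = 1)
    x <- array(runif(n * n * 3), c(n, n, 3, 1))
    out <- skullmark:::nn_forward(model$net, x, training = FALSE)$out
    expect_equal(dim(out), c(n, n, 2, 1))
    expect_equal(dim(skullmark:::nn_forward(
      model$net, x, training = FALSE)$outs[[model$blocks$bottleneck3]])[1:2],
      c(n / 16, n / 16))
  }
  expect_error(fcn_config(net_size = 100L), class = "skullmark_invalid_config")
})

test_that("building the same config twice gives identical parameters", {
  m1 <- build_fcn(fcn_config(64L, 0.25), seed = 5)
  m2 <- build_fcn(fcn_config(64L, 0.25), seed = 5)
  expect_identical(lapply(m1$net$nodes, `[[`, "par"),
                   lapply(m2$net$nodes, `[[`, "par"))
  expect_identical(skullmark:::nn_n_params(m1$net),
                   skullmark:::nn_n_params(m2$net))
})

test_that("bottleneck units follow the compress-process-expand design", {
  sp <- bottleneck_spec(32L, 128L)
  expect_equal(sp$internal_channels, 32L)      # 128 / 4
  expect_true(bottleneck_spec(64L, 64L, 1L)$identity_shortcut)
  expect_false(bottleneck_spec(64L, 64L, 2L)$identity_shortcut)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  # zero-residual limit: unit reduces to relu(identity shortcut)
  y <- bottleneck_forward(x, bottleneck_spec(8L, 8L, 1L), zero_weights = TRUE)
  expect_equal(y, array(pmax(x, 0), dim(x)), tolerance = 1e-12)
  # stride 2 halves the spatial size
  y2 <- bottleneck_forward(x, bottleneck_spec(8L, 16L, 2L), seed = 2)
  expect_equal(dim(y2), c(8, 8, 16, 2))
  expect_error(bottleneck_forward(x, bottleneck_spec(4L, 8L)),
               class = "skullmark_shape")
})

test_that("training-loop MSE equals a brute-force per-pixel sum", {
  set.seed(8)
  y <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  t <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  acc <- 0
  for (n in 1:3) for (ch in 1:2) for (r in 1:4) for (cc in 1:4)
    acc <- acc + (y[r, cc, ch, n] - t[r, cc, ch, n])^2
  expect_equal(skullmark:::mse_loss(y, t)$loss, acc / (4 * 4 * 2 * 3),
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a small net", {
  sm <- asNamespace("skullmark")
  set.seed(4)
  g <- sm$nn_graph()
  inp <- sm$nn_add(g, "input", shape = c(8L, 8L, 3L))
  out <- sm$add_bottleneck(g, inp, bottleneck_spec(3L, 8L, stride = 2L))
  out <- sm$nn_add(g, "deconv", out, k = 3L, stride = 2L, pad = 1L,
                   out_ch = 2L)
  ini <- sm$nn_init(g, NULL)
  net <- list(nodes = ini$nodes, out = out)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  cvec <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  fw <- sm$nn_forward(net, x, training = TRUE)
  grads <- sm$nn_backward(fw$net, fw, cvec)
  loss_of <- function(nn) sum(sm$nn_forward(nn, x, training = TRUE)$out * cvec)
  eps <- 1e-6
  for (id in seq_along(net$nodes)) {
    gp <- grads[[id]]
    if (is.null(gp)) next
    for (pn in names(gp)) {
      p <- net$nodes[[id]]$par[[pn]]
      for (k in sample(length(p), min(3, length(p)))) {
        n2 <- net
        n2$nodes[[id]]$par[[pn]][k] <- p[k] + eps
        lp <- loss_of(n2)
        n2$nodes[[id]]$par[[pn]][k] <- p[k] - eps
        lm <- loss_of(n2)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - gp[[pn]][k]) /
                    max(1, abs(fd), abs(gp[[pn]][k])), 1e-5)
      }
    }
  }
})

test_that("a zeroed final layer yields exactly zero output (degenerate fit)", {
  model <- build_fcn(fcn_config(32L, 0.25), seed = 1)
  last <- length(model$net$nodes)
  model$net$nodes[[last]]$par$W[] <- 0
  model$net$nodes[[last]]$par$b[] <- 0
  hm <- predict_heatmaps(model, array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_true(all(hm == 0))
  # loss against all-zero labels is exactly zero
  expect_identical(skullmark:::mse_loss(array(hm, c(32, 32, 2, 1)),
                                        array(0, c(32, 32, 2, 1)))$loss, 0)
})

test_that("training is deterministic and reduces the loss", {
  scenes <- scene_bank(16)
  pre <- skull_preset("tiny")
  pairs <- make_training_pairs(scenes[1:12], pre, spec = NULL)
  vpairs <- make_training_pairs(scenes[13:16], pre, spec = NULL)
  tc <- fcn_train_config(epochs = 3L, batch_size = 4L, seed = 11L)
  m1 <- train_fcn(pairs, vpairs, tc, fcn_config(64L, 0.25))
  m2 <- train_fcn(pairs, vpairs, tc, fcn_config(64L, 0.25))
  expect_identical(m1$history, m2$history)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  expect_equal(nrow(m1$history), 3)
  expect_true(all(is.finite(m1$history$val_loss)))
})

test_that("train_fcn validates its shapes", {
  pairs <- list(x = array(0, c(64, 64, 3, 4)), y = array(0, c(64, 64, 2, 3)))
  expect_error(train_fcn(pairs), class = "skullmark_shape")
  pairs2 <- list(x = array(0, c(64, 64, 3, 4)), y = array(0, c(32, 32, 2, 4)))
  expect_error(train_fcn(pairs2), class = "skullmark_shape")
})

test_that("flipping the input changes a random model's prediction (no built-in symmetry)", {
  model <- build_fcn(fcn_config(32L, 0.25), seed = 9)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  hm <- predict_heatmaps(model, x)
  hm_flip <- predict_heatmaps(model, x[, 32:1, ])[, 32:1, ]
  expect_gt(max(abs(hm - hm_flip)), 1e-8)
})

test_that("landmark prediction maps the argmax through the window scale", {
  model <- build_fcn(fcn_config(32L, 0.25), seed = 1)
  win <- crop_window(c(40, 60), crop_size = 80, net_size = 32)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_error(predict_landmarks(model, x, win), class = "skullmark_state")
  model$trained <- TRUE
  # constant output decodes to (0, 0) in the net frame by the tie-break
  last <- length(model$net$nodes)
  model$net$nodes[[last]]$par$W[] <- 0
  model$net$nodes[[last]]$par$b[] <- 0
  lm <- predict_landmarks(model, x, win)
  expect_identical(lm$bregma, c(0, 0))
  expect_identical(lm$frame, "crop")
  # upscale-then-argmax decode agrees for a constant map and stays in frame
  lm2 <- predict_landmarks(model, x, win, decode = "upscale_argmax")
  expect_identical(lm2$frame, "crop")
})

test_that("checkpoints round-trip through a single file", {
  model <- build_fcn(fcn_config(32L, 0.25), seed = 2)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$seed, model$seed)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_heatmaps(back, x), predict_heatmaps(model, x))
  unlink(path)
})
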