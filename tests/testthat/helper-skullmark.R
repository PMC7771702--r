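# Shared fixtures, built in code and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Bank of tiny-preset scenes with fixed seeds 1..n, shared across tests.
scene_bank <- function(n) {
  have <- .fixture_env$bank_n %||% 0L
  if (n > have) {
    more <- lapply((have + 1L):n, function(i)
      generate_scene(skull_scene_params(i, skull_preset("tiny"))))
    .fixture_env$bank <- c(.fixture_env$bank, more)
    .fixture_env$bank_n <- n
  }
  .fixture_env$bank[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bbox_iou <- function(a, b) {
  ir <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ic <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ir * ic
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Stub annotation frame (no images on disk) for bookkeeping tests.
stub_annotations <- function(n) {
  data.frame(image_path = sprintf("img_%03d.png", seq_len(n)),
             bbox_row0 = 10, bbox_col0 = 20, bbox_row1 = 110, bbox_col1 = 140,
             bregma_row = 40, bregma_col = 80, lambda_row = 80, lambda_col = 80)
}

# The scaled-down study protocol shared by the parameter-recovery and
# sigma-sweep checks: 200 training crops, 20 validation and 20 held-out
# scenes on the tiny preset, 30 epochs.  Scenes are streamed straight
# into (image, label) pairs — for both label widths at once — so only
# the 20 held-out scenes stay in memory.  Built lazily, once per run.
tiny_protocol <- function(seed = 1L) {
  memo("tiny_protocol", {
    pre <- skull_preset("tiny")
    ds <- skullmark:::derive_seed
    sig5_net <- 5 * pre$net_size / 256
    stream <- function(offset, n) {
      x <- array(0, c(pre$net_size, pre$net_size, 3L, n))
      y20 <- array(0, c(pre$net_size, pre$net_size, 2L, n))
      y5 <- y20
      for (i in seq_len(n)) {
        sc <- generate_scene(skull_scene_params(ds(seed, offset + i), pre))
        p20 <- make_training_pairs(list(sc), pre, spec = NULL)
        p5 <- make_training_pairs(list(sc), pre, spec = NULL,
                                  hm_config = heatmap_config(sigma = sig5_net))
        x[, , , i] <- p20$x[, , , 1L]
        y20[, , , i] <- p20$y[, , , 1L]
        y5[, , , i] <- p5$y[, , , 1L]
      }
      list(x = x, y20 = y20, y5 = y5)
    }
    tr <- stream(0L, 200L)
    va <- stream(100000L, 20L)
    test_scenes <- lapply(seq_len(20), function(i)
      generate_scene(skull_scene_params(ds(seed, 200000 + i), pre)))
    list(preset = pre, seed = seed,
         pairs20 = list(x = tr$x, y = tr$y20),
         vpairs20 = list(x = va$x, y = va$y20),
         pairs5 = list(x = tr$x, y = tr$y5),
         vpairs5 = list(x = va$x, y = va$y5),
         test = test_scenes)
  })
}

tiny_protocol_model <- function() {
  memo("tiny_protocol_model", {
    pr <- tiny_protocol()
    train_fcn(pr$pairs20, pr$vpairs20,
              fcn_train_config(epochs = 30L, batch_size = 8L, seed = pr$seed),
              config = fcn_config(pr$preset$net_size,
                                  pr$preset$width_multiplier))
  })
}
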