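test_that("localization error is the per-landmark Euclidean distance", {
  t <- landmark_set(c(10, 10), c(50, 50), frame = "crop")
  expect_equal(localization_error(t, t), c(bregma = 0, lambda = 0))
  p <- landmark_set(c(13, 14), c(50, 50), frame = "crop")
  expect_equal(localization_error(p, t)[["bregma"]], 5)   # 3-4-5 triangle
  p2 <- landmark_set(c(10, 10), c(50, 50), frame = "net")
  expect_error(localization_error(p2, t), class = "skullmark_frame")
})

test_that("batch means and maxima come out as plain arithmetic", {
  set.seed(13)
  errs <- numeric(13)
  t <- landmark_set(c(100, 100), c(60, 60), frame = "crop")
  for (i in 1:13) {
    off <- rnorm(2)
    p <- landmark_set(c(100, 100) + off, c(60, 60), frame = "crop")
    errs[i] <- localization_error(p, t)[["bregma"]]
  }
  expect_equal(mean(errs), sum(errs) / 13, tolerance = 1e-12)
  expect_equal(max(errs), sort(errs, decreasing = TRUE)[1])
})

test_that("pixel-micrometre calibration reproduces the printed conversion", {
  cal <- scale_calibration(4200, 163.20)
  expect_equal(round(cal$um_per_px, 2), 25.74)
  expect_equal(pixel_to_um(0, cal), 0)
  cal2 <- scale_calibration(4200, 4200 / 25.735)
  expect_equal(pixel_to_um(10, cal2), 257.35, tolerance = 1e-9)
  expect_error(scale_calibration(4200, 0), class = "skullmark_calibration")
  # unit consistency: doubling the physical distance doubles every value
  expect_equal(pixel_to_um(7, scale_calibration(8400, 163.2)),
               2 * pixel_to_um(7, scale_calibration(4200, 163.2)))
})

test_that("axis decomposition projects onto the tail-head / left-right axes", {
  pair <- landmark_set(c(100, 100), c(180, 100), frame = "crop")  # axis along rows
  # error parallel to the bregma-lambda axis has zero left-right part
  comp <- axis_decomposition(c(90, 100), c(100, 100), pair)
  expect_equal(comp[["left_right"]], 0)
  # with the axis along rows, components are just the (row, col) offsets
  comp2 <- axis_decomposition(c(103, 104), c(100, 100), pair)
  expect_equal(abs(unname(comp2)), c(3, 4))
  degenerate <- structure(list(bregma = c(1, 1), lambda = c(1, 1),
                               frame = "crop"), class = "landmark_set")
  expect_error(axis_decomposition(c(1, 2), c(1, 1), degenerate),
               class = "skullmark_axis")
})

test_that("squared components always reconstruct the squared error", {
  set.seed(21)
  for (k in 1:100) {
    pair <- landmark_set(runif(2, 0, 500), runif(2, 0, 500), frame = "crop")
    truth <- runif(2, 0, 500)
    pred <- truth + rnorm(2, 0, 20)
    comp <- axis_decomposition(pred, truth, pair)
    expect_equal(sum(comp^2), sum((pred - truth)^2), tolerance = 1e-6)
  }
})

test_that("pipeline evaluation keeps exact books over successes and failures", {
  pre <- skull_preset("tiny")
  scenes <- scene_bank(4)
  # one impossible scene: pure noise, so stage one must fail on it
  set.seed(2)
  noise_scene <- list(image = array(runif(612 * 816 * 3) * 40, c(612, 816, 3)),
                      bbox = c(200, 200, 400, 400),
                      landmarks = landmark_set(c(250, 250), c(300, 300)),
                      params = NULL)
  class(noise_scene) <- "annotated_image"
  model <- build_fcn(fcn_config(64L, 0.25), seed = 1)
  model$trained <- TRUE                      # random weights: books only
  ev <- evaluate_pipeline(c(scenes, list(noise_scene)),
                          roi_detector_baseline(), model, pre)
  expect_equal(ev$summary$failures + ev$summary$n_success, 5)
  expect_equal(nrow(ev$results), 2 * ev$summary$n_success)
  expect_true(all(c("bregma", "lambda") %in% ev$results$landmark))
  expect_true(all(ev$results$error_px >= 0))
  expect_equal(ev$results$error_px^2,
               ev$results$tail_head^2 + ev$results$left_right^2,
               tolerance = 1e-6)
  expect_gt(ev$summary$um_per_px, 0)
  # scatter export writes a file
  f <- tempfile(fileext = ".png")
  ev2 <- evaluate_pipeline(scenes, roi_detector_baseline(), model, pre,
                           scatter_png = f)
  expect_true(file.exists(f)); unlink(f)
})

test_that("sigma sweep produces one row per sigma, deterministically", {
  scenes <- scene_bank(10)
  tc <- fcn_train_config(epochs = 2L, batch_size = 4L, seed = 3L)
  tab <- sigma_sweep(scenes[1:8], scenes[9:10], sigmas = 20,
                     train_config = tc, preset = skull_preset("tiny"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$sigma_net, 5)             # 20 * 64 / 256
  tab2 <- sigma_sweep(scenes[1:8], scenes[9:10], sigmas = 20,
                      train_config = tc, preset = skull_preset("tiny"))
  expect_identical(tab, tab2)
  expect_true(all(is.finite(unlist(tab[, -1]))))
})
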