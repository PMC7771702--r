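test_that("downsampling is area-weighted and shape-exact", {
  m <- matrix(4.2, 2448, 3264)
  out <- downsample(m, 4L)
  expect_equal(dim(out), c(612, 816))
  expect_true(all(abs(out - 4.2) < 1e-12))      # mean-preserving on constants
  img <- array(runif(24 * 32 * 3), c(24, 32, 3))
  expect_identical(downsample(img, 1L), img)
  expect_error(downsample(img, 0L), class = "skullmark_invalid_config")
  # non-divisible size: edge-padded then resized, recorded
  odd <- matrix(1:35 / 35, 5, 7)
  out2 <- downsample(odd, 2L)
  expect_equal(dim(out2), c(3, 4))
  expect_equal(attr(out2, "padded"), c(1, 1))
})

test_that("baseline detector finds the skull with IoU >= 0.5 on synthetic scenes", {
  det <- roi_detector_baseline()
  ious <- vapply(scene_bank(8), function(sc) {
    low <- downsample(sc$image, 4L)
    d <- detect_skull(low, det)
    expect_s3_class(d, "roi_detection")
    expect_true(d$score >= 0 && d$score <= 1)
    bbox_iou(lowres_bbox_to_full(d$bbox_lowres, 4L), sc$bbox)
  }, numeric(1))
  expect_true(all(ious >= 0.5))
})

test_that("pure noise yields a no-detection error with diagnostics", {
  set.seed(1)
  noise <- array(runif(120 * 150 * 3) * 255, c(120, 150, 3))
  expect_error(detect_skull(noise, roi_detector_baseline()),
               class = "skullmark_no_detection")
})

test_that("a skull at the image margin still yields an in-bounds detection", {
  pre <- skull_preset("tiny")
  p <- skull_scene_params(4, pre)
  mar <- p$skull_axes[1] + 5
  p$skull_center <- c(mar, mar)           # push to the top-left corner
  sc <- generate_scene(p)
  low <- downsample(sc$image, 4L)
  d <- detect_skull(low, roi_detector_baseline())
  expect_true(all(d$bbox_lowres[1:2] >= 0))
  expect_lte(d$bbox_lowres[3], dim(low)[1])
  expect_lte(d$bbox_lowres[4], dim(low)[2])
})

clamp_expected <- function(org, sc) {
  d <- dim(sc$image)[1:2]
  pmin(pmax(org, 0), d - 160)
}

test_that("extract_net_input returns the right geometry", {
  sc <- scene_bank(1)[[1]]
  pre <- skull_preset("tiny")
  d <- detect_skull(downsample(sc$image, 4L), roi_detector_baseline())
  inp <- extract_net_input(sc$image, d, 4L, pre$crop_size, pre$net_size)
  expect_equal(dim(inp$net_image), c(64, 64, 3))
  expect_equal(dim(inp$crop), c(160, 160, 3))
  expect_equal(inp$window$scale, 2.5)
  # window corners map net -> full -> net exactly
  for (corner in list(c(0, 0), c(0, 63), c(63, 0), c(63, 63)))
    expect_identical(to_net(to_full(as.numeric(corner), inp$window),
                            inp$window), as.numeric(corner))
  # centred detection: origin = full-frame bbox centre - crop/2
  ctr_full <- (lowres_bbox_to_full(d$bbox_lowres, 4L)[1:2] +
               lowres_bbox_to_full(d$bbox_lowres, 4L)[3:4]) / 2
  expect_lte(max(abs(inp$window$origin -
                     clamp_expected(round(ctr_full - 80), sc))), 0)
})

test_that("the bbox regressor trains deterministically and transfers to held-out scenes", {
  scenes <- scene_bank(80)
  train_idx <- 1:60; test_idx <- 61:80
  ann <- do.call(rbind, lapply(scenes, function(sc) data.frame(
    image_path = NA, bbox_row0 = sc$bbox[1], bbox_col0 = sc$bbox[2],
    bbox_row1 = sc$bbox[3], bbox_col1 = sc$bbox[4],
    bregma_row = sc$landmarks$bregma[1], bregma_col = sc$landmarks$bregma[2],
    lambda_row = sc$landmarks$lambda[1], lambda_col = sc$landmarks$lambda[2])))
  imgs <- lapply(scenes, `[[`, "image")
  reg <- train_bbox_regressor(ann[train_idx, ], lowres_factor = 4L,
                              epochs = 20L, seed = 7L,
                              images = imgs[train_idx])
  ious <- vapply(test_idx, function(i) {
    d <- detect_skull(downsample(imgs[[i]], 4L), reg)
    bbox_iou(lowres_bbox_to_full(d$bbox_lowres, 4L), scenes[[i]]$bbox)
  }, numeric(1))
  expect_gte(mean(ious), 0.6)

  reg2 <- train_bbox_regressor(ann[1:12, ], lowres_factor = 4L,
                               epochs = 3L, seed = 7L,
                               images = imgs[1:12])
  reg3 <- train_bbox_regressor(ann[1:12, ], lowres_factor = 4L,
                               epochs = 3L, seed = 7L,
                               images = imgs[1:12])
  d1 <- detect_skull(downsample(imgs[[61]], 4L), reg2)
  d2 <- detect_skull(downsample(imgs[[61]], 4L), reg3)
  expect_identical(d1$bbox_lowres, d2$bbox_lowres)

  # only the training resolution is accepted
  expect_error(detect_skull(array(runif(80 * 80 * 3) * 255, c(80, 80, 3)), reg),
               class = "skullmark_shape")
  expect_error(train_bbox_regressor(ann[0, ]), class = "skullmark_data")
  expect_error(train_bbox_regressor(ann[1:5, ]), class = "skullmark_data")
})
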