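test_that("the identity draw reproduces the un-augmented crop and landmarks", {
  sc <- scene_bank(1)[[1]]
  pre <- skull_preset("tiny")
  win <- compute_crop_window(sc$bbox, dim(sc$image)[1:2],
                             pre$crop_size, pre$net_size)
  spec <- augment_spec(flip_prob = 0, rotation_range = c(0, 0),
                       shift_frac = 0)
  aug <- augment_once(sc$image, sc$landmarks, win, spec, draw_index = 1L,
                      seed = 3L)
  cn <- skullmark:::crop_to_net(sc$image, win)
  expect_equal(aug$crop, cn$crop, tolerance = 1e-12)
  lm_crop <- to_crop(sc$landmarks, win)
  expect_equal(aug$landmarks$bregma, lm_crop$bregma, tolerance = 1e-9)
  expect_equal(aug$landmarks$lambda, lm_crop$lambda, tolerance = 1e-9)
})

test_that("flips and rotations transform landmarks by the analytic formulas", {
  amp <- skullmark:::augment_map_point
  s <- 640
  # horizontal flip: col -> s - 1 - col, row unchanged
  d <- list(flip_h = TRUE, flip_v = FALSE, angle = 0, shift = c(0, 0))
  expect_equal(amp(c(120, 300), c(0, 0), s, d), c(120, s - 1 - 300))
  # vertical flip: row -> s - 1 - row
  d2 <- list(flip_h = FALSE, flip_v = TRUE, angle = 0, shift = c(0, 0))
  expect_equal(amp(c(120, 300), c(0, 0), s, d2), c(s - 1 - 120, 300))
  # 90-degree rotation about the crop centre matches the rotation matrix
  d3 <- list(flip_h = FALSE, flip_v = FALSE, angle = pi / 2, shift = c(0, 0))
  got <- amp(c(100, 200), c(0, 0), s, d3)
  ctr <- (s - 1) / 2
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  expect_lt(max(abs(got - (as.numeric(R %*% (c(100, 200) - ctr)) + ctr))), 0.5)
})

test_that("rotating image content agrees with rotating coordinates", {
  # put a bright dot at a known pixel, rotate, and find it where the
  # analytic map says it should be
  crop <- matrix(0, 160, 160)
  crop[41, 101] <- 100                      # 0-based (40, 100)
  rot <- skullmark:::rotate_crop(crop, pi / 3)
  peak <- which(rot == max(rot), arr.ind = TRUE)[1, ] - 1
  d <- list(flip_h = FALSE, flip_v = FALSE, angle = pi / 3, shift = c(0, 0))
  expected <- skullmark:::augment_map_point(c(40, 100), c(0, 0), 160, d)
  expect_lt(sqrt(sum((peak - expected)^2)), 1.0)
})

test_that("regenerated labels decode to the transformed landmarks", {
  pre <- skull_preset("tiny")
  scenes <- scene_bank(5)
  worst <- 0
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    win <- compute_crop_window(sc$bbox, dim(sc$image)[1:2],
                               pre$crop_size, pre$net_size)
    for (k in 1:12) {
      aug <- augment_once(sc$image, sc$landmarks, win, augment_spec(),
                          draw_index = k, seed = 100L + i)
      lm_net <- structure(list(bregma = aug$landmarks$bregma / 2.5,
                               lambda = aug$landmarks$lambda / 2.5,
                               frame = "net"), class = "landmark_set")
      lab <- make_label(c(64, 64), lm_net, heatmap_config(sigma = pre$sigma))
      dec <- decode_heatmap(unclass(lab))
      worst <- max(worst,
                   sqrt(sum((dec$bregma - lm_net$bregma)^2)),
                   sqrt(sum((dec$lambda - lm_net$lambda)^2)))
    }
  }
  expect_lt(worst, 1.0)
})

test_that("landmarks stay inside augmented crops; hopeless draws error", {
  pre <- skull_preset("tiny")
  sc <- scene_bank(2)[[2]]
  win <- compute_crop_window(sc$bbox, dim(sc$image)[1:2],
                             pre$crop_size, pre$net_size)
  for (k in 1:20) {
    aug <- augment_once(sc$image, sc$landmarks, win, augment_spec(),
                        draw_index = k, seed = 5L)
    expect_true(all(c(aug$landmarks$bregma, aug$landmarks$lambda) >= 0))
    expect_true(all(c(aug$landmarks$bregma, aug$landmarks$lambda) <= 159))
  }
  # an impossible margin exhausts the retry cap and names the draw
  bad_spec <- augment_spec(margin = 200)
  err <- tryCatch(augment_once(sc$image, sc$landmarks, win, bad_spec,
                               draw_index = 3L, seed = 5L),
                  error = identity)
  expect_s3_class(err, "skullmark_augmentation")
  expect_match(conditionMessage(err), "draw 3")
})

test_that("dataset expansion bookkeeping is exact", {
  plan80 <- expand_dataset(stub_annotations(80),
                           augment_spec(copies_per_image = 100L), seed = 1)
  expect_identical(nrow(plan80), 8000L)
  plan60 <- expand_dataset(stub_annotations(60),
                           augment_spec(copies_per_image = 100L), seed = 1)
  expect_identical(nrow(plan60), 6000L)
  plan1 <- expand_dataset(stub_annotations(7),
                          augment_spec(copies_per_image = 1L), seed = 1)
  expect_identical(nrow(plan1), 7L)
  expect_identical(plan1$image_path, stub_annotations(7)$image_path)
  # per-copy seeds are deterministic and distinct
  plan80b <- expand_dataset(stub_annotations(80),
                            augment_spec(copies_per_image = 100L), seed = 1)
  expect_identical(plan80, plan80b)
  expect_identical(anyDuplicated(plan80$aug_seed), 0L)
})

test_that("cross-validation folds follow the rotating layout without leakage", {
  ann <- stub_annotations(93)
  cv <- make_cv_folds(ann, cv_layout(), seed = 2)
  expect_equal(length(cv$folds), 4)
  test_ids <- cv$folds[[1]]$test
  for (k in 1:4) {
    f <- cv$folds[[k]]
    expect_equal(length(f$train), 60)
    expect_equal(length(f$val), 20)
    expect_equal(length(f$test), 13)
    expect_identical(f$test, test_ids)          # fixed test subset
    expect_length(intersect(f$test, c(f$train, f$val)), 0)
    expect_length(intersect(f$train, f$val), 0)
  }
  # every non-test image validates exactly once across folds
  val_all <- sort(unlist(lapply(cv$folds, `[[`, "val")))
  expect_identical(val_all, sort(setdiff(seq_len(93), test_ids)))
  # manifest mirrors the fold lists
  expect_identical(which(cv$manifest$fold_2 == "val"), cv$folds[[2]]$val)
})

test_that("undersized inputs are rejected by the fold builder", {
  expect_error(make_cv_folds(stub_annotations(4), cv_layout(), seed = 1),
               class = "skullmark_split")
})
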