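test_that("gaussian heatmap has the closed-form profile", {
  cfg <- heatmap_config(sigma = 20)
  hm <- make_gaussian_heatmap(c(256, 256), c(100, 100), cfg)
  # peak at the mean (0-based coords -> R index +1)
  expect_equal(hm[101, 101], 1.0, tolerance = 1e-12)
  # one sigma away: exp(-1/2)
  expect_equal(hm[121, 101] / hm[101, 101], exp(-0.5), tolerance = 1e-12)
  # beyond the truncation radius (60 px): exactly zero
  expect_identical(hm[251, 251], 0)
  expect_true(all(hm >= 0))
})

test_that("sub-pixel centres are evaluated exactly, peak only at pixel centres", {
  cfg <- heatmap_config(sigma = 5)
  hm <- make_gaussian_heatmap(c(64, 64), c(10.5, 20.25), cfg)
  expect_equal(hm[11, 21], exp(-(0.5^2 + 0.25^2) / (2 * 25)), tolerance = 1e-12)
  expect_lt(max(hm), 1.0)
})

test_that("off-grid centres write only the in-grid tail", {
  hm <- make_gaussian_heatmap(c(32, 32), c(-5, 16), heatmap_config(sigma = 5))
  expect_gt(max(hm), 0)
  expect_lt(max(hm), 1)
  hm_far <- make_gaussian_heatmap(c(32, 32), c(-100, -100),
                                  heatmap_config(sigma = 5))
  expect_identical(max(hm_far), 0)
})

test_that("invalid heatmap configs are rejected", {
  expect_error(heatmap_config(sigma = 0), class = "skullmark_invalid_config")
  expect_error(heatmap_config(sigma = -3), class = "skullmark_invalid_config")
  expect_error(heatmap_config(sigma = 5, truncation_radius = 2),
               class = "skullmark_invalid_config")
})

test_that("labels put bregma in channel 1, lambda in channel 2, independently", {
  lm <- landmark_set(c(64, 64), c(192, 64), frame = "net")
  lab <- make_label(c(256, 256), lm, heatmap_config(sigma = 20))
  expect_equal(dim(lab), c(256, 256, 2))
  expect_equal(lab[65, 65, 1], 1.0)
  expect_equal(lab[193, 65, 2], 1.0)
  # channels are independent even when the discs overlap
  lm2 <- landmark_set(c(100, 100), c(110, 100), frame = "net")
  lab2 <- make_label(c(256, 256), lm2, heatmap_config(sigma = 20))
  single <- make_gaussian_heatmap(c(256, 256), c(100, 100),
                                  heatmap_config(sigma = 20))
  expect_identical(lab2[, , 1], single)
})

test_that("nonzero support is the truncation disc", {
  # independent oracle: count integer points within radius 15 by brute force
  ctr <- c(100, 120)
  inside <- 0L
  for (r in 85:115) for (c in 105:135)
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 15^2) inside <- inside + 1L
  hm <- make_gaussian_heatmap(c(256, 256), ctr, heatmap_config(sigma = 5))
  expect_identical(sum(hm > 0), inside)
  expect_equal(inside, pi * 15^2, tolerance = 0.02)
})

test_that("label frame mismatch raises a frame error", {
  lm <- landmark_set(c(10, 10), c(20, 20), frame = "full")
  expect_error(make_label(c(64, 64), lm, frame = "net"),
               class = "skullmark_frame")
})

test_that("encode/decode identity holds across sigmas (exact argmax recovery)", {
  set.seed(42)
  for (sg in c(5, 10, 20, 40)) {
    cfg <- heatmap_config(sigma = sg)
    for (k in 1:25) {
      ctr <- c(sample(0:63, 1), sample(0:63, 1))
      ctr2 <- c(sample(0:63, 1), sample(0:63, 1))
      if (all(ctr2 == ctr)) ctr2 <- (ctr2 + 7) %% 64
      lm <- landmark_set(ctr, ctr2, frame = "net")
      dec <- decode_heatmap(unclass(make_label(c(64, 64), lm, cfg)))
      expect_identical(dec$bregma, as.numeric(ctr))
      expect_identical(dec$lambda, as.numeric(ctr2))
    }
  }
})

test_that("argmax ties break at the smallest row-major index", {
  const <- array(1, c(8, 8, 2))
  dec <- decode_heatmap(const)
  expect_identical(dec$bregma, c(0, 0))
  expect_identical(dec$lambda, c(0, 0))
  # two exact maxima: (2, 5) has row-major index 2*8+5 = 21, (3, 1) has 25
  m <- array(0, c(8, 8, 2))
  m[3, 6, 1] <- 1; m[4, 2, 1] <- 1   # 0-based (2,5) and (3,1)
  m[1, 1, 2] <- 1
  expect_identical(decode_heatmap(m)$bregma, c(2, 5))
})

test_that("decoding survives bounded uniform noise", {
  # noise amplitude below half the peak-to-runner-up gap keeps the argmax;
  # verified brute-force over a seeded draw
  cfg <- heatmap_config(sigma = 20)
  lm <- landmark_set(c(100, 150), c(40, 40), frame = "net")
  lab <- unclass(make_label(c(256, 256), lm, cfg))
  gap <- 1 * (1 - exp(-1 / (2 * 20^2)))
  set.seed(7)
  noisy <- lab + array(runif(length(lab), 0, gap / 2 * 0.99), dim(lab))
  dec <- decode_heatmap(noisy)
  expect_identical(dec$bregma, c(100, 150))
  expect_identical(dec$lambda, c(40, 40))
})

test_that("degenerate decode inputs error", {
  expect_error(decode_heatmap(matrix(1, 3, 3)), class = "skullmark_invalid_input")
  bad <- array(c(1, NA), c(4, 4, 2))
  expect_error(decode_heatmap(bad), class = "skullmark_invalid_input")
})

test_that("landmark_set validates its invariants", {
  expect_error(landmark_set(c(1, 2), c(1, 2)), class = "skullmark_invalid_config")
  expect_error(landmark_set(c(-1, 2), c(1, 2)), class = "skullmark_invalid_config")
  expect_error(landmark_set(c(Inf, 2), c(1, 2)), class = "skullmark_invalid_config")
})
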