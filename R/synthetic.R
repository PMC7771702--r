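# Seeded generator of skull-like scenes with exact analytic ground truth.
#
# The scene is parametric-geometry-first: bregma and lambda are points on
# the parametric suture curves, fixed before any pixel is rendered, so the
# stored annotation is exact by construction and never read back from
# pixels.  The rendered content emulates the structure of uncontrolled
# skull photographs: a bright elliptical skull on a darker textured
# background, a sagittal midline suture, a coronal suture crossing it at
# bregma (arms bowing toward the nose), a lambdoid suture crossing at
# lambda (arms sweeping caudally), optional dark vessel distractors along
# the midline, a linear lighting ramp, arbitrary orientation, and additive
# pixel noise.  The coronal/lambdoid shape difference plus a subtle
# anterior brightening of the frontal bone are the cues that break the
# 180-degree symmetry of the landmark pair, as suture shape and bone
# texture do in real skulls.

#' Draw the parameters of one synthetic skull scene
#'
#' All randomness of the scene geometry is drawn here from `seed`;
#' rendering noise is derived from the same seed inside
#' [generate_scene()].  Named overrides (e.g. `orientation = 0`) replace
#' the drawn value while leaving every other draw untouched, which makes
#' controlled experiments (same skull, different orientation) possible.
#'
#' @param seed Integer scene seed.
#' @param preset A [skull_preset()] (or its name).
#' @param ... Overrides for drawn fields: `orientation` (radians),
#'   `bl_distance`, `skull_center`, `skull_axes`, `noise_sd`,
#'   `vessel_count`, `light_strength`, and friends.
#' @return A list of class `skull_scene_params`.
#' @export
skull_scene_params <- function(seed, preset = skull_preset("full"), ...) {
  if (is.character(preset)) preset <- skull_preset(preset)
  H <- preset$canvas[1L]; W <- preset$canvas[2L]
  p <- with_seed(seed, {
    d <- runif(1, preset$bl_distance_range[1L], preset$bl_distance_range[2L])
    a <- d * runif(1, 1.15, 1.35)          # semi-axis along the midline
    b <- a * runif(1, 0.60, 0.75)          # transverse semi-axis
    mar <- a + 12 * preset$scale
    list(
      image_shape = c(H, W),
      bl_distance = d,
      skull_axes = c(a, b),
      skull_center = c(runif(1, mar, H - mar), runif(1, mar, W - mar)),
      orientation = runif(1, 0, 2 * pi),
      pair_offset = runif(1, -0.08, 0.08) * a,
      bg_level = runif(1, 50, 80),
      skull_level = runif(1, 165, 200),
      texture_amp = runif(1, 5, 12),
      light_dir = runif(1, 0, 2 * pi),
      light_strength = runif(1, 0, 35),
      anterior_shade = runif(1, 8, 18),
      noise_sd = 5,
      stroke_sigma = 2.5,
      suture_depth = runif(1, 45, 65),
      wobble_amp = runif(1, 0, 2),
      coronal_bow = runif(1, 0.35, 0.55),
      lambdoid_slope = runif(1, 0.55, 0.80),
      vessel_count = sample(0:3, 1),
      vessel_depth = runif(1, 20, 35)
    )
  })
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad))
    stop_skullmark("parameter", paste("unknown parameter override:",
                                      paste(bad, collapse = ", ")))
  p[names(ov)] <- ov
  p$seed <- as.integer(seed)
  p$preset <- preset
  structure(p, class = "skull_scene_params")
}

# Midline direction (lambda -> bregma, i.e. towards the nose) and its
# left-right perpendicular, as (row, col) unit vectors.
scene_axes <- function(params) {
  th <- params$orientation
  list(u = c(cos(th), sin(th)), v = c(-sin(th), cos(th)))
}

# Analytic landmark positions implied by the scene parameters.
scene_landmarks <- function(params) {
  ax <- scene_axes(params)
  ctr <- params$skull_center + params$pair_offset * ax$u
  landmark_set(bregma = ctr + (params$bl_distance / 2) * ax$u,
               lambda = ctr - (params$bl_distance / 2) * ax$u,
               frame = "full")
}

# Dense sample points of the three suture curves in the full frame.
# Each curve passes exactly through its landmark(s) by parameterization.
# `step` overrides the sample spacing (rendering uses the stroke width;
# analytic re-derivation uses a much finer grid).
scene_curves <- function(params, step = NULL) {
  ax <- scene_axes(params); u <- ax$u; v <- ax$v
  a <- params$skull_axes[1L]; b <- params$skull_axes[2L]
  lm <- scene_landmarks(params)
  off <- params$pair_offset
  pc <- params$skull_center + off * u      # landmark-pair centre
  h <- step %||% (0.6 * params$stroke_sigma)  # sample spacing along curves
  d2 <- params$bl_distance / 2

  tt <- seq(-0.97 * a - off, 0.97 * a - off, by = h)
  wob <- params$wobble_amp * sin(pi * (tt - d2) / (-2 * d2))  # 0 at both landmarks
  midline <- cbind(pc[1L] + tt * u[1L] + wob * v[1L],
                   pc[2L] + tt * u[2L] + wob * v[2L])

  Lc <- 0.75 * b
  ll <- seq(-Lc, Lc, by = h)
  fwd <- params$coronal_bow * ll^2 / Lc    # smooth arc bowing anteriorly
  coronal <- cbind(lm$bregma[1L] + ll * v[1L] + fwd * u[1L],
                   lm$bregma[2L] + ll * v[2L] + fwd * u[2L])

  Ll <- 0.70 * b
  ll2 <- seq(-Ll, Ll, by = h)
  bwd <- params$lambdoid_slope * abs(ll2)  # chevron sweeping caudally
  lambdoid <- cbind(lm$lambda[1L] + ll2 * v[1L] - bwd * u[1L],
                    lm$lambda[2L] + ll2 * v[2L] - bwd * u[2L])

  list(midline = midline, coronal = coronal, lambdoid = lambdoid,
       sample_step = h)
}

# Quadratic form q(p) of the egg-shaped skull outline; q < 1 inside.
# The transverse half-width shrinks towards the anterior (nasal) end and
# widens posteriorly — the gross head/tail asymmetry every skull
# photograph shows — via b_eff = b * (1 - egg * tu/a).
skull_egg_factor <- 0.22

ellipse_q <- function(pts, params) {
  ax <- scene_axes(params)
  dr <- pts[, 1L] - params$skull_center[1L]
  dc <- pts[, 2L] - params$skull_center[2L]
  tu <- dr * ax$u[1L] + dc * ax$u[2L]
  tv <- dr * ax$v[1L] + dc * ax$v[2L]
  a <- params$skull_axes[1L]
  beff <- params$skull_axes[2L] * pmax(0.3, 1 - skull_egg_factor * tu / a)
  (tu / a)^2 + (tv / beff)^2
}

# Splat a sampled curve into the darkness accumulator D (element-wise max
# against what is already there).  `h` is the sample spacing; the sum of
# Gaussian cross-sections spaced h apart approximates a constant ridge of
# height sqrt(2*pi)*sigma/h, which is normalized away so the stroke depth
# is uniform along the curve.
splat_curve <- function(D, pts, sigma, depth, h) {
  if (nrow(pts) == 0L) return(D)
  Hn <- nrow(D); Wn <- ncol(D)
  rad <- ceiling(3 * sigma)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  m <- nrow(pts); K <- nrow(offs)
  pr <- rep(pts[, 1L], times = K); pc <- rep(pts[, 2L], times = K)
  R0 <- round(pr) + rep(offs$dr, each = m)
  C0 <- round(pc) + rep(offs$dc, each = m)
  keep <- R0 >= 0 & R0 < Hn & C0 >= 0 & C0 < Wn
  if (!any(keep)) return(D)
  R0 <- R0[keep]; C0 <- C0[keep]; pr <- pr[keep]; pc <- pc[keep]
  w <- exp(-((R0 - pr)^2 + (C0 - pc)^2) / (2 * sigma^2))
  use <- w > 0.004
  idx <- (R0[use] + C0[use] * Hn) + 1
  agg <- rowsum(w[use], idx)
  val <- depth * pmin(agg[, 1L] / (sqrt(2 * pi) * sigma / h), 1.15)
  ui <- as.integer(rownames(agg))
  D[ui] <- pmax(D[ui], val)
  D
}

#' Render one annotated synthetic skull scene
#'
#' @param params A [skull_scene_params()].
#' @return An object of class `annotated_image`: list with `image`
#'   (`H x W x 3` array, values in `[0, 255]`), `bbox` (tight axis-aligned
#'   box of the skull ellipse, `(r0, c0, r1, c1)` with exclusive upper
#'   edges), `landmarks` (full-frame [landmark_set()]) and `params`.
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "skull_scene_params"))
    stop_skullmark("parameter", "params must come from skull_scene_params()")
  H <- params$image_shape[1L]; W <- params$image_shape[2L]
  lm <- tryCatch(scene_landmarks(params),
                 skullmark_invalid_config = function(e)
                   stop_skullmark("parameter", paste(
                     "parameters place landmarks outside the image:",
                     conditionMessage(e))))
  qlm <- ellipse_q(rbind(lm$bregma, lm$lambda), params)
  if (any(qlm >= 0.9))
    stop_skullmark("parameter", "landmarks fall too close to the skull edge")
  if (any(c(lm$bregma, lm$lambda) < 0) ||
      any(lm$bregma >= c(H, W)) || any(lm$lambda >= c(H, W)))
    stop_skullmark("parameter", "landmarks fall outside the image")

  ax <- scene_axes(params)
  rr <- seq_len(H) - 1; cc <- seq_len(W) - 1
  dr <- rr - params$skull_center[1L]; dc <- cc - params$skull_center[2L]
  tu <- outer(dr * ax$u[1L], dc * ax$u[2L], `+`)
  tv <- outer(dr * ax$v[1L], dc * ax$v[2L], `+`)
  a_ax <- params$skull_axes[1L]
  beff <- params$skull_axes[2L] * pmax(0.3, 1 - skull_egg_factor * tu / a_ax)
  q <- (tu / a_ax)^2 + (tv / beff)^2

  img <- with_seed(derive_seed(params$seed, 777L), {
    base <- matrix(params$bg_level, H, W)
    for (k in 1:3) {                      # low-frequency background texture
      fr <- runif(1, 0.5, 3) / H; fc <- runif(1, 0.5, 3) / W
      ph <- runif(1, 0, 2 * pi)
      base <- base + (params$texture_amp / 3) *
        sin(2 * pi * outer(rr * fr, cc * fc, `+`) + ph)
    }
    ramp <- outer(dr * cos(params$light_dir), dc * sin(params$light_dir), `+`)
    base <- base + params$light_strength * ramp / sqrt(H^2 + W^2)

    wrim <- clamp((1 - q) / 0.08, 0, 1)   # soft skull rim
    skull <- params$skull_level +
      params$anterior_shade * (tu / params$skull_axes[1L])
    gray <- base * (1 - wrim) + skull * wrim

    crv <- scene_curves(params)
    D <- matrix(0, H, W)
    for (nm in c("midline", "coronal", "lambdoid")) {
      pts <- crv[[nm]]
      pts <- pts[ellipse_q(pts, params) < 0.95, , drop = FALSE]
      D <- splat_curve(D, pts, params$stroke_sigma, params$suture_depth,
                       crv$sample_step)
    }
    if (params$vessel_count > 0) {
      for (j in seq_len(params$vessel_count)) {
        voff <- sample(c(-1, 1), 1) * runif(1, 2.5, 8) * params$stroke_sigma
        ext <- runif(1, 0.3, 0.6) * params$skull_axes[1L]
        t0 <- runif(1, -0.3, 0.3) * params$skull_axes[1L]
        h <- 0.6 * params$stroke_sigma
        tt <- seq(t0 - ext, t0 + ext, by = h)
        wig <- runif(1, 1, 3) * sin(tt / runif(1, 8, 25) + runif(1, 0, 2 * pi))
        pc2 <- params$skull_center + params$pair_offset * ax$u
        pts <- cbind(pc2[1L] + tt * ax$u[1L] + (voff + wig) * ax$v[1L],
                     pc2[2L] + tt * ax$u[2L] + (voff + wig) * ax$v[2L])
        pts <- pts[ellipse_q(pts, params) < 0.9, , drop = FALSE]
        D <- splat_curve(D, pts, 1.2, params$vessel_depth, h)
      }
    }
    gray <- gray - D

    tint <- c(1.02, 0.95, 0.87)           # bone-like warm tint
    out <- array(0, c(H, W, 3L))
    for (ch in 1:3)
      out[, , ch] <- clamp(gray * tint[ch] +
                             matrix(rnorm(H * W, 0, params$noise_sd), H, W),
                           0, 255)
    out
  })

  # tight axis-aligned box of the egg outline, from sampled boundary points
  s <- seq(0, 2 * pi, length.out = 721L)[-721L]
  btu <- params$skull_axes[1L] * cos(s)
  btv <- params$skull_axes[2L] * (1 - skull_egg_factor * cos(s)) * sin(s)
  brow <- params$skull_center[1L] + btu * ax$u[1L] + btv * ax$v[1L]
  bcol <- params$skull_center[2L] + btu * ax$u[2L] + btv * ax$v[2L]
  bbox <- c(max(0, floor(min(brow))), max(0, floor(min(bcol))),
            min(H, ceiling(max(brow))), min(W, ceiling(max(bcol))))

  structure(list(image = img, bbox = bbox, landmarks = lm, params = params),
            class = "annotated_image")
}

#' Re-derive the landmarks as suture-curve intersections
#'
#' Independent geometric check of the stored annotations: numerically
#' intersects the rendered midline curve with the coronal and lambdoid
#' curves (the same parametric curves that were splatted into pixels) and
#' returns the two intersection points.
#'
#' @param params A [skull_scene_params()].
#' @return A full-frame [landmark_set()] of the intersection points.
#' @export
rederive_landmarks <- function(params) {
  crv <- scene_curves(params, step = 0.1)
  nearest <- function(aa, bb) {
    # brute-force closest sample pair, then exact intersection of the
    # local line segments (accurate to O(step^2) for smooth curves)
    best <- c(Inf, 0, 0)
    for (i in seq_len(nrow(aa))) {
      d2 <- (bb[, 1L] - aa[i, 1L])^2 + (bb[, 2L] - aa[i, 2L])^2
      j <- which.min(d2)
      if (d2[j] < best[1L]) best <- c(d2[j], i, j)
    }
    i <- best[2L]; j <- best[3L]
    # the curves may have a corner at the crossing (the lambdoid apex), so
    # test every adjacent segment pair and keep the intersection whose
    # parameters lie closest to [0, 1] on both segments
    segs_a <- list(c(max(1L, i - 1L), i), c(i, min(nrow(aa), i + 1L)))
    segs_b <- list(c(max(1L, j - 1L), j), c(j, min(nrow(bb), j + 1L)))
    fallback <- (aa[i, ] + bb[j, ]) / 2
    best_pt <- fallback; best_score <- Inf
    for (sa in segs_a) for (sb in segs_b) {
      p1 <- aa[sa[1L], ]; p2 <- aa[sa[2L], ]
      q1 <- bb[sb[1L], ]; q2 <- bb[sb[2L], ]
      A <- cbind(p2 - p1, -(q2 - q1))
      if (abs(det(A)) < 1e-12) next
      ts <- solve(A, q1 - p1)
      score <- max(0, ts[1L] - 1, -ts[1L], ts[2L] - 1, -ts[2L])
      if (score < best_score) {
        best_score <- score
        best_pt <- p1 + ts[1L] * (p2 - p1)
      }
    }
    best_pt
  }
  landmark_set(bregma = nearest(crv$midline, crv$coronal),
               lambda = nearest(crv$midline, crv$lambdoid),
               frame = "full")
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n` scenes as PNG images plus the annotation CSV and a manifest
#' YAML recording the preset, the master seed and every per-scene seed
#' (derived by the counter scheme `derive_seed(seed, i)`, so a dataset can
#' be extended without reshuffling existing scenes).
#'
#' @param n Number of scenes.
#' @param split Named fractions `c(train =, val =, test =)` summing to 1.
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param preset A [skull_preset()] or its name.
#' @param write_images Set `FALSE` to skip PNG rendering and only write
#'   annotations (images are then regenerated on demand from the seeds).
#' @return The annotation data frame (invisibly), with columns
#'   `image_path`, `bbox_row0`, `bbox_col0`, `bbox_row1`, `bbox_col1`,
#'   `bregma_row`, `bregma_col`, `lambda_row`, `lambda_col`, `split`,
#'   `scene_seed`.
#' @export
generate_dataset <- function(n, split = c(train = 60 / 93, val = 20 / 93,
                                          test = 13 / 93),
                             seed = 1L, dir = tempfile("skullset"),
                             preset = skull_preset("full"),
                             write_images = TRUE) {
  if (is.character(preset)) preset <- skull_preset(preset)
  if (abs(sum(split) - 1) > 1e-8)
    stop_skullmark("split", "split fractions must sum to 1")
  k <- sum(split > 0)
  if (n < k)
    stop_skullmark("split", sprintf("%d images cannot fill %d splits", n, k))
  counts <- floor(n * split)
  rem <- n - sum(counts)
  if (rem > 0) {                      # distribute remainders to largest splits
    ord <- order(n * split - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  roles <- rep(names(split), counts)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    sc <- generate_scene(skull_scene_params(si, preset))
    path <- file.path(dir, sprintf("scene_%03d.png", i))
    if (write_images)
      png::writePNG(sc$image / 255, path)
    rows[[i]] <- data.frame(
      image_path = path,
      bbox_row0 = sc$bbox[1L], bbox_col0 = sc$bbox[2L],
      bbox_row1 = sc$bbox[3L], bbox_col1 = sc$bbox[4L],
      bregma_row = sc$landmarks$bregma[1L], bregma_col = sc$landmarks$bregma[2L],
      lambda_row = sc$landmarks$lambda[1L], lambda_col = sc$landmarks$lambda[2L],
      split = roles[i], scene_seed = si,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  write_annotations(ann, file.path(dir, "annotations.csv"))
  yaml::write_yaml(list(preset = preset$name, n = n, seed = as.integer(seed),
                        split = as.list(split),
                        scene_seeds = ann$scene_seed),
                   file.path(dir, "manifest.yaml"))
  invisible(ann)
}
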