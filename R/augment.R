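# Label-consistent flip / rotate / shift augmentation of skull crops.
#
# The crop window is shifted within the full image, the cropped content is
# rotated about the crop centre and optionally flipped; the landmark
# coordinates are transformed by the same analytic composition and the
# heatmap labels are regenerated in the augmented frame (never resampled
# from pixels, which would bias the supervision).

#' Augmentation specification
#'
#' @param flip_prob Probability of each of the horizontal and vertical
#'   flips (0.5).
#' @param rotation_range Rotation angle range in radians, drawn uniformly
#'   (default the full circle, since the photographed orientations are
#'   uncontrolled).
#' @param shift_frac Crop-window translation range per axis as a fraction
#'   of the crop size (default 0.10, keeping the skull in frame).
#' @param copies_per_image Augmented copies drawn per training image
#'   (study value 100).
#' @param retry_cap Maximum redraws when a transformed landmark leaves the
#'   crop (then a `skullmark_augmentation` error names the draw).
#' @param margin Minimum landmark distance from the crop border, px.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(flip_prob = 0.5, rotation_range = c(0, 2 * pi),
                         shift_frac = 0.10, copies_per_image = 100L,
                         retry_cap = 25L, margin = 2) {
  structure(list(flip_prob = flip_prob, rotation_range = rotation_range,
                 shift_frac = shift_frac,
                 copies_per_image = as.integer(copies_per_image),
                 retry_cap = as.integer(retry_cap), margin = margin),
            class = "augment_spec")
}

# One draw of augmentation parameters.
draw_augment <- function(spec, crop_size) {
  list(flip_h = stats::runif(1) < spec$flip_prob,
       flip_v = stats::runif(1) < spec$flip_prob,
       angle = stats::runif(1, spec$rotation_range[1L],
                            spec$rotation_range[2L]),
       shift = round(stats::runif(2, -1, 1) * spec$shift_frac * crop_size))
}

# Apply the analytic coordinate map of a draw to full-frame points:
# translate into the shifted crop, rotate about the crop centre, flip.
augment_map_point <- function(p_full, origin, crop_size, draw) {
  ctr <- (crop_size - 1) / 2
  p <- p_full - origin
  th <- draw$angle
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  p <- as.numeric(R %*% (p - ctr)) + ctr
  if (draw$flip_h) p[2L] <- crop_size - 1 - p[2L]
  if (draw$flip_v) p[1L] <- crop_size - 1 - p[1L]
  p
}

# Rotate crop content by `angle` about its centre (bilinear sampling,
# edge replication): output pixel p reads the input at R(-angle)(p-c)+c.
rotate_crop <- function(crop, angle) {
  if (angle == 0) return(crop)
  d <- dim(crop)
  s <- d[1L]
  ctr <- (s - 1) / 2
  rr <- rep(seq_len(s) - 1 - ctr, times = s)
  cc <- rep(seq_len(s) - 1 - ctr, each = s)
  sr <- cos(angle) * rr + sin(angle) * cc + ctr
  sc <- -sin(angle) * rr + cos(angle) * cc + ctr
  r0 <- clamp(floor(sr), 0, s - 1); c0 <- clamp(floor(sc), 0, s - 1)
  fr <- clamp(sr - r0, 0, 1); fc <- clamp(sc - c0, 0, 1)
  r1 <- pmin(r0 + 1, s - 1); c1 <- pmin(c0 + 1, s - 1)
  i00 <- r0 + c0 * s + 1; i01 <- r0 + c1 * s + 1
  i10 <- r1 + c0 * s + 1; i11 <- r1 + c1 * s + 1
  out <- array(0, d)
  nch <- if (length(d) == 3L) d[3L] else 1L
  for (ch in seq_len(nch)) {
    m <- if (length(d) == 3L) crop[, , ch] else crop
    v <- (1 - fr) * (1 - fc) * m[i00] + (1 - fr) * fc * m[i01] +
      fr * (1 - fc) * m[i10] + fr * fc * m[i11]
    if (length(d) == 3L) out[, , ch] <- v else out <- array(v, d)
  }
  out
}

flip_crop <- function(crop, flip_h, flip_v) {
  if (flip_h) crop <- if (length(dim(crop)) == 3L)
    crop[, rev(seq_len(dim(crop)[2L])), , drop = FALSE]
  else crop[, rev(seq_len(ncol(crop))), drop = FALSE]
  if (flip_v) crop <- if (length(dim(crop)) == 3L)
    crop[rev(seq_len(dim(crop)[1L])), , , drop = FALSE]
  else crop[rev(seq_len(nrow(crop))), , drop = FALSE]
  crop
}

#' Produce one augmented crop with consistent landmarks
#'
#' Draws flip/rotation/shift parameters from the seed derived for
#' `(image, draw_index)`, shifts the crop window, rotates the content
#' about the crop centre, flips, and transforms the landmarks by the same
#' analytic composition.  Draws that would push a landmark within
#' `spec$margin` of the crop border are redrawn up to `spec$retry_cap`
#' times.
#'
#' @param full_image Full-resolution image array.
#' @param landmarks Full-frame [landmark_set()].
#' @param base_window [crop_window()] from stage one or the ground-truth
#'   bbox.
#' @param spec An [augment_spec()].
#' @param draw_index Index of this draw (with `seed` it determines the
#'   draw).
#' @param seed Per-image augmentation seed.
#' @return List with `crop`, `landmarks` (crop-frame), `window` (the
#'   shifted [crop_window()]) and `draw` (the accepted parameters).
#' @export
augment_once <- function(full_image, landmarks, base_window,
                         spec = augment_spec(), draw_index = 1L,
                         seed = 1L) {
  stopifnot(inherits(base_window, "crop_window"))
  if (landmarks$frame != "full")
    stop_skullmark("frame", "augment_once expects full-frame landmarks")
  s <- base_window$crop_size
  for (attempt in seq_len(spec$retry_cap)) {
    draw <- with_seed(derive_seed(seed, draw_index * 1000L + attempt),
                      draw_augment(spec, s))
    origin <- base_window$origin + draw$shift
    b <- augment_map_point(landmarks$bregma, origin, s, draw)
    l <- augment_map_point(landmarks$lambda, origin, s, draw)
    if (all(c(b, l) >= spec$margin) && all(c(b, l) <= s - 1 - spec$margin)) {
      crop <- extract_window(full_image, origin, s)
      crop <- rotate_crop(crop, draw$angle)
      crop <- flip_crop(crop, draw$flip_h, draw$flip_v)
      lm <- structure(list(bregma = b, lambda = l, frame = "crop"),
                      class = "landmark_set")
      win <- crop_window(origin, s, base_window$net_size)
      return(list(crop = crop, landmarks = lm, window = win, draw = draw,
                  attempts = attempt))
    }
  }
  stop_skullmark("augmentation", sprintf(
    "draw %d: landmarks expelled from the crop %d times in a row",
    draw_index, spec$retry_cap))
}

#' Expand a training set into an augmentation plan
#'
#' Produces the deterministic plan of `n_images x copies_per_image`
#' augmentation draws (the augmentation log): one row per augmented item
#' with its derived seed.  Images are materialized lazily by
#' [augment_once()]/[make_training_pairs()], so the plan itself is cheap
#' even for thousands of items.
#'
#' @param train_annotations Annotation data frame of the training images.
#' @param spec An [augment_spec()].
#' @param seed Master augmentation seed.
#' @return A data frame with columns `image_index`, `image_path`, `copy`,
#'   `aug_seed`.
#' @export
expand_dataset <- function(train_annotations, spec = augment_spec(),
                           seed = 1L) {
  if (spec$copies_per_image < 1L)
    stop_skullmark("invalid_config", "copies_per_image must be >= 1")
  n <- nrow(train_annotations)
  plan <- expand.grid(copy = seq_len(spec$copies_per_image),
                      image_index = seq_len(n))[, 2:1]
  plan$image_path <- train_annotations$image_path[plan$image_index]
  plan$aug_seed <- derive_seed(seed, plan$image_index * 100000L + plan$copy)
  rownames(plan) <- NULL
  plan[, c("image_index", "image_path", "copy", "aug_seed")]
}

#' Assemble (net image, heatmap label) training pairs
#'
#' For each requested (scene, copy) the ground-truth crop window is
#' computed from the annotated bbox, augmented per `spec` (pass
#' `spec = NULL` for un-augmented pairs), area-downsampled to the net
#' size, and the label regenerated analytically in the net frame.
#'
#' @param scenes List of `annotated_image` objects (or annotation rows
#'   with loadable `image_path`s).
#' @param preset A [skull_preset()].
#' @param hm_config [heatmap_config()]; default uses the preset's sigma.
#' @param spec [augment_spec()] or `NULL`.
#' @param copies Copies per scene (1 when `spec` is `NULL`).
#' @param seed Master seed for the augmentation draws.
#' @return List with `x` (`net, net, 3, N`) and `y` (`net, net, 2, N`).
#' @export
make_training_pairs <- function(scenes, preset = skull_preset("tiny"),
                                hm_config = NULL, spec = augment_spec(),
                                copies = 1L, seed = 1L) {
  if (is.null(hm_config)) hm_config <- heatmap_config(sigma = preset$sigma)
  n <- length(scenes)
  N <- n * copies
  ns <- preset$net_size
  x <- array(0, c(ns, ns, 3L, N))
  y <- array(0, c(ns, ns, 2L, N))
  k <- 0L
  for (i in seq_len(n)) {
    sc <- scenes[[i]]
    base_win <- compute_crop_window(sc$bbox, dim(sc$image)[1:2],
                                    crop_size = preset$crop_size,
                                    net_size = preset$net_size)
    for (cp in seq_len(copies)) {
      k <- k + 1L
      if (is.null(spec)) {
        cn <- crop_to_net(sc$image, base_win)
        lm_crop <- to_crop(sc$landmarks, base_win)
        crop <- cn$crop
        win <- base_win
      } else {
        aug <- augment_once(sc$image, sc$landmarks, base_win, spec,
                            draw_index = cp, seed = derive_seed(seed, i))
        crop <- aug$crop
        lm_crop <- aug$landmarks
        win <- aug$window
      }
      x[, , , k] <- resize_image(crop, c(ns, ns), "area") / 255
      lm_net <- structure(list(bregma = lm_crop$bregma / win$scale,
                               lambda = lm_crop$lambda / win$scale,
                               frame = "net"),
                          class = "landmark_set")
      y[, , , k] <- unclass(make_label(c(ns, ns), lm_net, hm_config,
                                       frame = "net"))
    }
  }
  list(x = x, y = y)
}
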