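# Stage one: detect the skull in a downsampled image and extract the
# fixed-size full-resolution crop for the refinement network.
#
# Skull detection is behind a small S3 interface (`predict_roi`) so any
# external object detector can be plugged in.  Two detectors ship with
# the package: a deterministic rule-based baseline (smooth, Otsu
# threshold, largest connected component) and a small seeded
# convolutional bounding-box regressor trained on synthetic scenes.

#' Downsample an image by an integer factor
#'
#' Area-weighted (mean-preserving) downsampling; images whose size is not
#' divisible by `factor` are edge-padded first and the padding recorded in
#' attribute `padded`.
#'
#' @param image `H x W x C` array or `H x W` matrix.
#' @param factor Integer >= 1.
#' @return The downsampled image.
#' @export
downsample <- function(image, factor = 4L) {
  if (!is_scalar_num(factor) || factor < 1)
    stop_skullmark("invalid_config", "factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  d <- dim(image)
  padr <- (factor - d[1L] %% factor) %% factor
  padc <- (factor - d[2L] %% factor) %% factor
  if (padr > 0 || padc > 0) {         # edge-replicate to divisibility
    ri <- clamp(seq_len(d[1L] + padr) - 1L, 0L, d[1L] - 1L) + 1L
    ci <- clamp(seq_len(d[2L] + padc) - 1L, 0L, d[2L] - 1L) + 1L
    image <- if (length(d) == 2L) image[ri, ci, drop = FALSE]
             else image[ri, ci, , drop = FALSE]
  }
  out <- resize_image(image, c(dim(image)[1L] %/% factor,
                               dim(image)[2L] %/% factor), "area")
  if (padr > 0 || padc > 0) attr(out, "padded") <- c(padr, padc)
  out
}

#' Skull detection result
#'
#' @param bbox_lowres `(r0, c0, r1, c1)` in the low-resolution frame
#'   (0-based, exclusive upper edges).
#' @param score Confidence in `[0, 1]`.
#' @param detector_id Name of the detector that produced it.
#' @param image_shape Low-resolution `(H, W)` used for bounds checking.
#' @return An object of class `roi_detection`.
#' @export
roi_detection <- function(bbox_lowres, score, detector_id,
                          image_shape = NULL) {
  bbox_lowres <- as.numeric(bbox_lowres)
  if (bbox_lowres[1L] >= bbox_lowres[3L] || bbox_lowres[2L] >= bbox_lowres[4L])
    stop_skullmark("invalid_bbox", "detection bbox has non-positive extent")
  if (!is.null(image_shape) &&
      (any(bbox_lowres[1:2] < 0) || bbox_lowres[3L] > image_shape[1L] ||
       bbox_lowres[4L] > image_shape[2L]))
    stop_skullmark("invalid_bbox", "detection bbox outside image bounds")
  structure(list(bbox_lowres = bbox_lowres,
                 score = clamp(score, 0, 1),
                 detector_id = detector_id),
            class = "roi_detection")
}

#' Detector interface
#'
#' `predict_roi(detector, lowres_image)` must return a single
#' [roi_detection()] (the highest-scoring candidate) or signal a
#' `skullmark_no_detection` condition.
#'
#' @param detector A detector object.
#' @param lowres_image Low-resolution `H x W x 3` array (values 0-255).
#' @param ... Passed to methods.
#' @export
predict_roi <- function(detector, lowres_image, ...) {
  UseMethod("predict_roi")
}

#' Detect the skull region in a low-resolution image
#'
#' Thin wrapper over [predict_roi()] that validates the single-detection
#' contract (exactly one skull per image).
#'
#' @inheritParams predict_roi
#' @return A [roi_detection()].
#' @export
detect_skull <- function(lowres_image, detector) {
  det <- predict_roi(detector, lowres_image)
  if (!inherits(det, "roi_detection"))
    stop_skullmark("invalid_input", "detector did not return an roi_detection")
  det
}

#' Rule-based baseline skull detector
#'
#' Deterministic oracle for synthetic scenes: grayscale, Gaussian smooth,
#' Otsu threshold, take the largest connected component brighter than the
#' background and return its bounding box.  The score is the normalized
#' foreground/background contrast.
#'
#' @param smooth_sigma Gaussian blur standard deviation in low-res pixels.
#' @param min_area_frac,max_area_frac Plausible skull area range as a
#'   fraction of the image; outside it a `skullmark_no_detection` error is
#'   signalled.
#' @param min_contrast Minimum normalized contrast for a detection.
#' @return A detector for [detect_skull()].
#' @export
roi_detector_baseline <- function(smooth_sigma = 3, min_area_frac = 0.005,
                                  max_area_frac = 0.6, min_contrast = 0.08) {
  structure(list(smooth_sigma = smooth_sigma,
                 min_area_frac = min_area_frac,
                 max_area_frac = max_area_frac,
                 min_contrast = min_contrast),
            class = c("roi_detector_baseline", "roi_detector"))
}

#' @export
predict_roi.roi_detector_baseline <- function(detector, lowres_image, ...) {
  d <- dim(lowres_image)
  gray <- if (length(d) == 3L)
    (lowres_image[, , 1L] + lowres_image[, , 2L] + lowres_image[, , 3L]) / 3
  else lowres_image
  gray01 <- gray / 255
  sm <- EBImage::gblur(gray01, sigma = detector$smooth_sigma)
  # flatten uncontrolled illumination: subtract a very smooth background
  # estimate (coarse area average, bilinearly re-expanded)
  coarse <- resize_matrix(sm, c(max(4L, nrow(sm) %/% 64L),
                                max(4L, ncol(sm) %/% 64L)), "area")
  bg <- resize_matrix(coarse, dim(sm), "bilinear")
  sm <- sm - bg
  thr <- EBImage::otsu(sm - min(sm), range = c(0, max(sm) - min(sm)))
  mask <- (sm - min(sm)) > thr
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 1L)
    stop_skullmark("no_detection", "no foreground component found")
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  best <- which.max(areas)
  frac <- areas[best] / length(gray)
  comp <- lab == best
  idx <- which(comp, arr.ind = TRUE)
  contrast <- mean(sm[comp]) - mean(sm[!comp])
  if (frac < detector$min_area_frac || frac > detector$max_area_frac ||
      contrast < detector$min_contrast)
    stop_skullmark("no_detection", sprintf(
      "largest component implausible (area %.3f%%, contrast %.3f)",
      100 * frac, contrast))
  bbox <- c(min(idx[, 1L]) - 1L, min(idx[, 2L]) - 1L,
            max(idx[, 1L]), max(idx[, 2L]))
  roi_detection(bbox, score = clamp(contrast * 2, 0, 1),
                detector_id = "baseline-otsu",
                image_shape = dim(gray))
}

# ---- convolutional bounding-box regressor -------------------------------

# Regressor input: grayscale rendering of the low-resolution image,
# squeezed to a fixed square (the normalized-coordinate bookkeeping
# absorbs the aspect distortion).
roi_reg_input <- function(lowres_image, input_size) {
  d <- dim(lowres_image)
  gray <- if (length(d) == 3L)
    (lowres_image[, , 1L] + lowres_image[, , 2L] + lowres_image[, , 3L]) / 3
  else lowres_image
  array(resize_matrix(gray / 255, c(input_size, input_size), "area"),
        c(input_size, input_size, 1L))
}

# Dense supervision target: the bbox as a binary mask on the score-map
# grid (map pixel centres, normalized coordinates).
roi_reg_mask <- function(bbox, shape, map_size) {
  r <- (seq_len(map_size) - 0.5) / map_size          # normalized centres
  cc <- (seq_len(map_size) - 0.5) / map_size
  rin <- r >= bbox[1L] / shape[1L] & r <= bbox[3L] / shape[1L]
  cin <- cc >= bbox[2L] / shape[2L] & cc <= bbox[4L] / shape[2L]
  outer(rin, cin) * 1
}

# (centre, log-size) of the box read from the non-negative part of a
# score map by first/second moments; a uniform box of height h has
# sd = h / sqrt(12).
roi_reg_decode <- function(map, shape) {
  w <- pmax(map, 0)
  w[w < 0.4 * max(w)] <- 0      # drop diffuse background response
  tot <- sum(w)
  if (tot < 1e-6)
    stop_skullmark("no_detection", "score map has no positive response")
  m <- nrow(map)
  r <- (seq_len(m) - 0.5) / m
  pr <- rowSums(w) / tot; pc <- colSums(w) / tot
  cr <- sum(pr * r); ccn <- sum(pc * r)
  sdr <- sqrt(sum(pr * (r - cr)^2)); sdc <- sqrt(sum(pc * (r - ccn)^2))
  list(center = c(cr, ccn) * shape,
       log_size = log(pmax(sqrt(12) * c(sdr, sdc), 2 / m)),
       strength = tot / m^2)
}

roi_reg_bbox <- function(dec, shape) {
  half <- exp(dec$log_size) * shape / 2
  c(clamp(dec$center[1L] - half[1L], 0, shape[1L] - 2),
    clamp(dec$center[2L] - half[2L], 0, shape[2L] - 2),
    clamp(dec$center[1L] + half[1L], 1, shape[1L]),
    clamp(dec$center[2L] + half[2L], 1, shape[2L]))
}

build_roi_regressor_net <- function(input_size) {
  # a small fully convolutional scorer trained against the bbox mask:
  # dense per-pixel supervision trains orders of magnitude better than a
  # 4-number regression target on these small datasets.  Batch-norm-free
  # (the map's absolute level carries meaning at inference).
  g <- nn_graph()
  inp <- nn_add(g, "input", shape = c(input_size, input_size, 1L))
  x <- nn_conv_bn_relu(g, inp, 16L, k = 3L, stride = 2L, bn = FALSE)
  x <- nn_conv_bn_relu(g, x, 32L, k = 3L, stride = 1L, bn = FALSE)
  x <- nn_conv_bn_relu(g, x, 32L, k = 3L, stride = 1L, bn = FALSE)
  out <- nn_add(g, "conv", x, k = 1L, stride = 1L, pad = 0L, out_ch = 1L)
  list(g = g, out = out)
}

#' Train the convolutional bounding-box regressor
#'
#' A small convolutional network trained to score skull-ness per
#' location (dense supervision against the annotated box mask); at
#' detection time the box's (centre, log-size) are read from the first
#' and second moments of the thresholded score map.  Deterministic given
#' the seed.  The detector only accepts images of the low-resolution
#' shape it was trained at.
#'
#' @param train_annotations Annotation data frame ([read_annotations()])
#'   with full-frame bboxes; images are loaded from `image_path`.
#' @param lowres_factor Downsampling factor from full to detection frame.
#' @param input_size Side length of the regressor input (default 64).
#' @param epochs,batch_size,learning_rate Training hyper-parameters.
#' @param seed RNG seed for init and shuffling.
#' @param images Optional list of full-resolution images (bypasses
#'   `image_path` loading; index-aligned with the annotation rows).
#' @return A detector of class `roi_regressor` for [detect_skull()].
#' @export
train_bbox_regressor <- function(train_annotations, lowres_factor = 4L,
                                 input_size = 64L, epochs = 20L,
                                 batch_size = 8L, learning_rate = 0.001,
                                 seed = 1L, images = NULL) {
  n <- nrow(train_annotations)
  if (is.null(n) || n < 1L)
    stop_skullmark("data", "empty training set")
  if (n < 10L)
    stop_skullmark("data", "need at least 10 annotated images")
  map_size <- input_size %/% 2L
  xs <- array(0, c(input_size, input_size, 1L, n))
  ys <- array(0, c(map_size, map_size, 1L, n))
  lowres_shape <- NULL
  for (i in seq_len(n)) {
    img <- if (!is.null(images)) images[[i]]
           else load_image(train_annotations$image_path[i])
    low <- downsample(img, lowres_factor)
    if (is.null(lowres_shape)) lowres_shape <- dim(low)[1:2]
    xs[, , , i] <- roi_reg_input(low, input_size)
    ys[, , 1L, i] <- roi_reg_mask(ann_bbox(train_annotations[i, ]) /
                                    lowres_factor,
                                  lowres_shape, map_size)
  }
  spec <- build_roi_regressor_net(input_size)
  fit <- with_seed(seed, {
    ini <- nn_init(spec$g, NULL)
    nn_fit(list(nodes = ini$nodes, out = spec$out), xs, ys,
           epochs = epochs, batch_size = batch_size, lr = learning_rate)
  })
  structure(list(net = fit$net, history = fit$history,
                 input_size = as.integer(input_size),
                 lowres_shape = as.integer(lowres_shape),
                 lowres_factor = as.integer(lowres_factor),
                 seed = as.integer(seed)),
            class = c("roi_regressor", "roi_detector"))
}

#' @export
predict_roi.roi_regressor <- function(detector, lowres_image, ...) {
  d <- dim(lowres_image)[1:2]
  if (!identical(as.integer(d), detector$lowres_shape))
    stop_skullmark("shape", sprintf(
      "regressor was trained at %d x %d, got %d x %d",
      detector$lowres_shape[1L], detector$lowres_shape[2L], d[1L], d[2L]))
  x <- array(roi_reg_input(lowres_image, detector$input_size),
             c(detector$input_size, detector$input_size, 1L, 1L))
  map <- nn_forward(detector$net, x, training = FALSE)$out[, , 1L, 1L]
  dec <- roi_reg_decode(map, d)
  roi_detection(roi_reg_bbox(dec, d),
                score = clamp(dec$strength * 20, 0, 1),
                detector_id = "conv-bbox-regressor", image_shape = d)
}

#' Extract the network input for a detected skull
#'
#' Maps the low-resolution detection to the full frame, computes the
#' fixed-size crop window centred on it, and returns the area-downsampled
#' network input together with the window for inverse mapping.
#'
#' @param full_image Full-resolution `H x W x 3` array.
#' @param detection A [roi_detection()].
#' @param lowres_factor Factor between the detection and full frames.
#' @param crop_size,net_size Crop geometry (defaults 640 / 256).
#' @return List with `net_image` (`net_size` square, `[0, 255]`), `crop`,
#'   and `window` (a [crop_window()]).
#' @export
extract_net_input <- function(full_image, detection, lowres_factor = 4L,
                              crop_size = 640L, net_size = 256L) {
  stopifnot(inherits(detection, "roi_detection"))
  bbox_full <- lowres_bbox_to_full(detection$bbox_lowres, lowres_factor)
  window <- compute_crop_window(bbox_full, dim(full_image)[1:2],
                                crop_size = crop_size, net_size = net_size)
  cn <- crop_to_net(full_image, window)
  list(net_image = cn$net, crop = cn$crop, window = window)
}

#' Load an image file as a 0-255 array
#'
#' @param path PNG/JPEG/TIFF path (PNG and TIFF supported natively).
#' @return `H x W x 3` array with values in `[0, 255]`.
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_skullmark("invalid_input", paste("unsupported image format:", ext)))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}
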