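# Localization-error metrics, pixel-to-micrometre calibration, per-axis
# error decomposition, the sigma-sweep experiment, and end-to-end
# pipeline evaluation.
#
# Errors are reported in the crop frame (full-resolution pixel pitch),
# where the bregma-lambda distance calibrates the micrometre conversion.

#' Pixel-to-micrometre calibration
#'
#' @param physical_distance_um Physical bregma-lambda distance in
#'   micrometres (adult-mouse value 4200).
#' @param pixel_distance Bregma-lambda distance in evaluation-frame
#'   pixels (study value about 163.20 at full resolution).
#' @return An object of class `scale_calibration` with the derived
#'   `um_per_px` conversion.
#' @export
scale_calibration <- function(physical_distance_um = 4200,
                              pixel_distance = 163.20) {
  if (!is_scalar_num(pixel_distance) || pixel_distance <= 0 ||
      !is_scalar_num(physical_distance_um) || physical_distance_um <= 0)
    stop_skullmark("calibration", "distances must be positive")
  structure(list(physical_distance_um = physical_distance_um,
                 pixel_distance = pixel_distance,
                 um_per_px = physical_distance_um / pixel_distance),
            class = "scale_calibration")
}

#' Convert a pixel error to micrometres
#'
#' @param error_px Error(s) in pixels.
#' @param cal A [scale_calibration()].
#' @export
pixel_to_um <- function(error_px, cal) {
  stopifnot(inherits(cal, "scale_calibration"))
  if (cal$um_per_px <= 0)
    stop_skullmark("calibration", "non-positive conversion")
  error_px * cal$um_per_px
}

#' Euclidean localization error per landmark
#'
#' @param pred,truth [landmark_set()]s in the same frame.
#' @return Named numeric `c(bregma =, lambda =)` in pixels.
#' @export
localization_error <- function(pred, truth) {
  if (pred$frame != truth$frame)
    stop_skullmark("frame", sprintf("frames differ: '%s' vs '%s'",
                                    pred$frame, truth$frame))
  c(bregma = sqrt(sum((pred$bregma - truth$bregma)^2)),
    lambda = sqrt(sum((pred$lambda - truth$lambda)^2)))
}

#' Decompose a localization error along anatomical axes
#'
#' The tail-head axis is the normalized ground-truth bregma-minus-lambda
#' direction; left-right is its perpendicular.  The returned components
#' are signed projections of (predicted - true) onto those axes, so their
#' squares sum to the squared Euclidean error.
#'
#' @param pred,truth Predicted and true coordinates of one landmark
#'   (`(row, col)`).
#' @param truth_pair Ground-truth [landmark_set()] defining the axes.
#' @return Named numeric `c(tail_head =, left_right =)`.
#' @export
axis_decomposition <- function(pred, truth, truth_pair) {
  u <- truth_pair$bregma - truth_pair$lambda
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9)
    stop_skullmark("axis", "coincident bregma/lambda cannot define axes")
  u <- u / nu
  v <- c(-u[2L], u[1L])
  e <- pred - truth
  c(tail_head = sum(e * u), left_right = sum(e * v))
}

summarize_errors <- function(results) {
  agg <- lapply(split(results$error_px, results$landmark),
                function(e) c(mean = mean(e), max = max(e)))
  agg
}

#' Evaluate the full two-stage pipeline on test scenes
#'
#' Runs stage one (downsample, detect, crop) and stage two (FCN, argmax
#' decode) per scene, compares predictions with the exact ground truth in
#' the crop frame, converts to micrometres using a calibration computed
#' from the mean ground-truth bregma-lambda pixel distance of the test
#' set (override with `cal`), and decomposes errors along the tail-head /
#' left-right axes.  Scenes where stage one signals no detection are
#' tallied as failures and excluded from the means.
#'
#' @param scenes List of `annotated_image` objects.
#' @param roi_detector A detector for [detect_skull()].
#' @param fcn_model A trained `skullmark_fcn`.
#' @param preset The [skull_preset()] the scenes were generated with.
#' @param cal Optional fixed [scale_calibration()].
#' @param physical_distance_um Physical bregma-lambda distance used when
#'   calibrating from the data.
#' @param scatter_png Optional path: writes a scatter plot of the signed
#'   error components per landmark.
#' @return List of class `pipeline_evaluation`: `results` (one row per
#'   scene x landmark), `summary` (mean/max per landmark in px and um,
#'   failure count), `calibration`, `failures`.
#' @export
evaluate_pipeline <- function(scenes, roi_detector, fcn_model,
                              preset = skull_preset("tiny"), cal = NULL,
                              physical_distance_um = 4200,
                              scatter_png = NULL) {
  if (is.null(cal)) {
    dists <- vapply(scenes, function(sc)
      sqrt(sum((sc$landmarks$bregma - sc$landmarks$lambda)^2)), numeric(1))
    cal <- scale_calibration(physical_distance_um, mean(dists))
  }
  rows <- list(); failures <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    det <- tryCatch(
      detect_skull(downsample(sc$image, preset$lowres_factor), roi_detector),
      skullmark_no_detection = function(e) NULL)
    if (is.null(det)) { failures <- failures + 1L; next }
    inp <- extract_net_input(sc$image, det,
                             lowres_factor = preset$lowres_factor,
                             crop_size = preset$crop_size,
                             net_size = preset$net_size)
    pred <- predict_landmarks(fcn_model, inp$net_image, inp$window)
    truth <- to_crop(sc$landmarks, inp$window)
    err <- localization_error(pred, truth)
    for (lmk in c("bregma", "lambda")) {
      comp <- axis_decomposition(pred[[lmk]], truth[[lmk]], truth)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = i, landmark = lmk,
        pred_row = pred[[lmk]][1L], pred_col = pred[[lmk]][2L],
        true_row = truth[[lmk]][1L], true_col = truth[[lmk]][2L],
        error_px = unname(err[lmk]),
        error_um = unname(pixel_to_um(err[lmk], cal)),
        tail_head = unname(comp["tail_head"]),
        left_right = unname(comp["left_right"]))
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = integer(), landmark = character(),
               error_px = numeric())
  summary <- list(failures = failures, n_scenes = length(scenes),
                  n_success = length(scenes) - failures,
                  frame = "crop", um_per_px = cal$um_per_px)
  if (nrow(results)) {
    for (lmk in c("bregma", "lambda")) {
      e <- results$error_px[results$landmark == lmk]
      summary[[lmk]] <- list(mean_px = mean(e), max_px = max(e),
                             mean_um = mean(e) * cal$um_per_px,
                             max_um = max(e) * cal$um_per_px)
    }
  }
  if (!is.null(scatter_png) && nrow(results)) {
    grDevices::png(scatter_png, width = 900, height = 480)
    graphics::par(mfrow = c(1, 2))
    for (lmk in c("bregma", "lambda")) {
      sub <- results[results$landmark == lmk, ]
      lim <- max(abs(c(sub$tail_head, sub$left_right, 1))) * 1.1
      plot(sub$left_right, sub$tail_head, pch = 16,
           xlim = c(-lim, lim), ylim = c(-lim, lim),
           xlab = "left-right error (px)", ylab = "tail-head error (px)",
           main = lmk)
      graphics::points(0, 0, pch = 3, col = "red", cex = 2)
    }
    grDevices::dev.off()
  }
  structure(list(results = results, summary = summary, calibration = cal,
                 failures = failures),
            class = "pipeline_evaluation")
}

#' Sigma sweep: localization error versus label standard deviation
#'
#' Trains one FCN per label standard deviation with identical seeds and
#' identical data, then evaluates each on the held-out pairs by argmax
#' decoding.  Sigmas are given in 256-net-equivalent pixels and scaled by
#' `net_size / 256` internally, so `sigma = 5` on a 64-net trains with a
#' 1.25-px label.
#'
#' @param train_pairs,test_scenes Training pairs
#'   ([make_training_pairs()]) and held-out `annotated_image` scenes.
#' @param sigmas Label standard deviations (256-equivalent px).
#' @param train_config An [fcn_train_config()].
#' @param preset The [skull_preset()] in use.
#' @param scenes_train Training scenes; labels are regenerated per sigma.
#' @return Data frame: one row per sigma with mean/max crop-frame error
#'   per landmark.
#' @export
sigma_sweep <- function(scenes_train, test_scenes, sigmas = c(5, 10, 20, 40),
                        train_config = fcn_train_config(epochs = 30L),
                        preset = skull_preset("tiny")) {
  out <- list()
  for (sg in sigmas) {
    sg_net <- sg * preset$net_size / 256
    pairs <- make_training_pairs(scenes_train, preset,
                                 hm_config = heatmap_config(sigma = sg_net),
                                 spec = NULL)
    model <- train_fcn(pairs, val_pairs = NULL, train_config = train_config,
                       config = fcn_config(preset$net_size,
                                           preset$width_multiplier))
    ev <- evaluate_with_gt_windows(test_scenes, model, preset)
    out[[length(out) + 1L]] <- data.frame(
      sigma = sg, sigma_net = sg_net,
      bregma_mean_px = ev$bregma["mean"], bregma_max_px = ev$bregma["max"],
      lambda_mean_px = ev$lambda["mean"], lambda_max_px = ev$lambda["max"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Evaluate a trained FCN on scenes using ground-truth crop windows
# (isolates stage-two error from detector error).  Errors in crop px.
evaluate_with_gt_windows <- function(scenes, model, preset) {
  eb <- c(); el <- c()
  for (sc in scenes) {
    win <- compute_crop_window(sc$bbox, dim(sc$image)[1:2],
                               crop_size = preset$crop_size,
                               net_size = preset$net_size)
    cn <- crop_to_net(sc$image, win)
    pred <- predict_landmarks(model, cn$net, win)
    truth <- to_crop(sc$landmarks, win)
    err <- localization_error(pred, truth)
    eb <- c(eb, err["bregma"]); el <- c(el, err["lambda"])
  }
  list(bregma = c(mean = mean(eb), max = max(eb)),
       lambda = c(mean = mean(el), max = max(el)))
}
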