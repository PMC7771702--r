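# Coordinate-frame bookkeeping: the crop window object and the exact maps
# between network, crop, low-resolution and full-resolution frames.
#
# Bounding boxes are numeric (r0, c0, r1, c1), 0-based with exclusive
# upper edges, so (0, 0, 612, 816) is the whole 612 x 816 image.

#' Crop-window geometry
#'
#' Records where a fixed-size skull crop sits in the full-resolution image
#' and how much the crop is downsampled for the network, so predictions can
#' be mapped back exactly.
#'
#' @param origin `(row, col)` of the crop's top-left corner in the
#'   full-resolution frame (integer-valued; may be negative when the image
#'   is smaller than the crop and edge-padding applies).
#' @param crop_size Side length of the square crop in full-resolution
#'   pixels (default 640).
#' @param net_size Side length after downsampling for the network
#'   (default 256); `crop_size / net_size` is the exact coordinate scale
#'   (2.5 at the defaults).
#' @return An object of class `crop_window`.
#' @export
crop_window <- function(origin, crop_size = 640, net_size = 256) {
  origin <- as.numeric(origin)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop_skullmark("invalid_config", "origin must be finite (row, col)")
  if (!is_scalar_num(crop_size) || crop_size <= 0 ||
      !is_scalar_num(net_size) || net_size <= 0)
    stop_skullmark("invalid_config", "crop_size and net_size must be positive")
  structure(list(origin = origin, crop_size = crop_size, net_size = net_size,
                 scale = crop_size / net_size),
            class = "crop_window")
}

#' @export
print.crop_window <- function(x, ...) {
  cat(sprintf("<crop_window> origin (%g, %g), crop %g, net %g (scale %g)\n",
              x$origin[1], x$origin[2], x$crop_size, x$net_size, x$scale))
  invisible(x)
}

#' Map net-frame coordinates to the full-resolution frame
#'
#' `full = origin + coord * (crop_size / net_size)`.  Coordinates outside
#' `[0, net_size)` are allowed (extrapolation) but flagged with a warning.
#'
#' @param coord `(row, col)` in the net frame, or a [landmark_set()] in
#'   frame `"net"`.
#' @param window A [crop_window()].
#' @return Coordinates (or a `landmark_set` in frame `"full"`).
#' @export
to_full <- function(coord, window) {
  stopifnot(inherits(window, "crop_window"))
  if (inherits(coord, "landmark_set")) {
    if (coord$frame != "net")
      stop_skullmark("frame", "to_full expects landmarks in the 'net' frame")
    out <- list(bregma = to_full(coord$bregma, window),
                lambda = to_full(coord$lambda, window), frame = "full")
    return(structure(out, class = "landmark_set"))
  }
  if (any(coord < 0) || any(coord >= window$net_size))
    warning("coordinate outside the net frame; extrapolating")
  window$origin + coord * window$scale
}

#' Map full-resolution coordinates into the net frame
#'
#' Exact inverse of [to_full()]: `net = (full - origin) / scale`.
#'
#' @inheritParams to_full
#' @param coord `(row, col)` in the full frame, or a full-frame
#'   [landmark_set()].
#' @export
to_net <- function(coord, window) {
  stopifnot(inherits(window, "crop_window"))
  if (inherits(coord, "landmark_set")) {
    if (coord$frame != "full")
      stop_skullmark("frame", "to_net expects landmarks in the 'full' frame")
    out <- list(bregma = to_net(coord$bregma, window),
                lambda = to_net(coord$lambda, window), frame = "net")
    return(structure(out, class = "landmark_set"))
  }
  (coord - window$origin) / window$scale
}

#' Map full-resolution coordinates into the crop frame
#'
#' The crop frame shares the full-resolution pixel pitch; the map is a pure
#' translation by the window origin.
#'
#' @inheritParams to_full
#' @param coord Coordinates or a full-frame [landmark_set()].
#' @export
to_crop <- function(coord, window) {
  stopifnot(inherits(window, "crop_window"))
  if (inherits(coord, "landmark_set")) {
    if (coord$frame != "full")
      stop_skullmark("frame", "to_crop expects landmarks in the 'full' frame")
    out <- list(bregma = coord$bregma - window$origin,
                lambda = coord$lambda - window$origin, frame = "crop")
    return(structure(out, class = "landmark_set"))
  }
  coord - window$origin
}

#' Scale a low-resolution bounding box back to the full frame
#'
#' @param bbox `(r0, c0, r1, c1)`, 0-based, exclusive upper edges.
#' @param factor Integer downsampling factor that produced the
#'   low-resolution frame (default 4).
#' @return The bbox with every coordinate multiplied by `factor`.
#' @export
lowres_bbox_to_full <- function(bbox, factor = 4L) {
  if (!is_scalar_num(factor) || factor < 1)
    stop_skullmark("invalid_config", "factor must be >= 1")
  as.numeric(bbox) * factor
}

#' Compute the fixed-size crop window around a detected skull box
#'
#' Centres a `crop_size` window on the bbox centre, then translates it the
#' minimum distance needed to lie inside the image.  When the image is
#' smaller than the crop along an axis the window is centred and the
#' extraction edge-replicates out-of-range pixels (the window keeps its
#' fixed size, which the network requires).
#'
#' @param bbox_full Skull bbox `(r0, c0, r1, c1)` in the full frame.
#' @param image_shape `(H, W)` of the full image.
#' @param crop_size Side length of the crop (default 640).
#' @param net_size Network input side length (default 256).
#' @return A [crop_window()].
#' @export
compute_crop_window <- function(bbox_full, image_shape, crop_size = 640,
                                net_size = 256) {
  bbox_full <- as.numeric(bbox_full)
  if (bbox_full[3L] <= bbox_full[1L] || bbox_full[4L] <= bbox_full[2L])
    stop_skullmark("invalid_bbox", "bbox has zero area")
  H <- image_shape[1L]; W <- image_shape[2L]
  if (bbox_full[1L] >= H || bbox_full[2L] >= W ||
      bbox_full[3L] <= 0 || bbox_full[4L] <= 0)
    stop_skullmark("invalid_bbox", "bbox does not intersect the image")
  ctr <- c((bbox_full[1L] + bbox_full[3L]) / 2,
           (bbox_full[2L] + bbox_full[4L]) / 2)
  org <- round(ctr - crop_size / 2)
  clamp1 <- function(o, n) {
    if (n >= crop_size) clamp(o, 0, n - crop_size)
    else round((n - crop_size) / 2)      # image smaller than crop: centre it
  }
  crop_window(c(clamp1(org[1L], H), clamp1(org[2L], W)),
              crop_size = crop_size, net_size = net_size)
}

#' Extract the network input for a crop window
#'
#' Cuts the `crop_size` square (edge-replicating where the window leaves
#' the image) and area-downsamples it to `net_size`.
#'
#' @param image Full-resolution `H x W x C` array (or `H x W` matrix).
#' @param window A [crop_window()].
#' @return List with `crop` (crop-frame pixels) and `net` (net-frame
#'   pixels).
#' @keywords internal
crop_to_net <- function(image, window) {
  crop <- extract_window(image, window$origin, window$crop_size)
  net <- resize_image(crop, c(window$net_size, window$net_size), "area")
  list(crop = crop, net = net)
}
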