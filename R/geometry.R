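#' Landmark pair in a named coordinate frame
#'
#' Bundles the bregma and lambda pixel coordinates together with the
#' coordinate frame they live in.  All coordinates in the package are
#' 0-based `(row, col)` pairs with the origin at the top-left pixel centre;
#' sub-pixel positions are allowed everywhere except heatmap decoding,
#' which is integer-pixel by construction.
#'
#' @param bregma,lambda Numeric `(row, col)` coordinates of the two
#'   landmarks.  Bregma is the anterior point (sagittal x coronal suture
#'   intersection), lambda the posterior one (sagittal x lambdoid).
#' @param frame One of `"full"`, `"lowres"`, `"crop"`, `"net"`: the raw
#'   full-resolution image, its downsampled version used for skull
#'   detection, the fixed-size skull crop, and the network input frame.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(bregma, lambda,
                         frame = c("full", "lowres", "crop", "net")) {
  frame <- match.arg(frame)
  bregma <- as.numeric(bregma); lambda <- as.numeric(lambda)
  if (length(bregma) != 2L || length(lambda) != 2L ||
      !all(is.finite(c(bregma, lambda))))
    stop_skullmark("invalid_config", "landmark coordinates must be finite length-2")
  if (any(c(bregma, lambda) < 0))
    stop_skullmark("invalid_config", "landmark coordinates must be non-negative")
  if (all(bregma == lambda))
    stop_skullmark("invalid_config", "bregma and lambda must be distinct")
  structure(list(bregma = bregma, lambda = lambda, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set [%s]> bregma (%.2f, %.2f)  lambda (%.2f, %.2f)\n",
              x$frame, x$bregma[1], x$bregma[2], x$lambda[1], x$lambda[2]))
  invisible(x)
}

#' Gaussian heatmap label configuration
#'
#' The supervision target for the refinement network is, per landmark, an
#' un-normalized 2-D Gaussian bump centred on the landmark: value
#' `peak * exp(-d^2 / (2 sigma^2))` for pixels within `truncation_radius`
#' of the centre and exactly 0 beyond it.  The default standard deviation
#' of 20 px refers to the 256 x 256 network frame; the tiny test preset
#' scales it to 5 px.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param peak Amplitude at the centre (> 0).
#' @param truncation_radius Distance beyond which values are exactly 0;
#'   defaults to `3 * sigma` (captures > 98.9\% of the mass and keeps the
#'   label sparse).
#' @return An object of class `heatmap_config`.
#' @export
heatmap_config <- function(sigma = 20, peak = 1,
                           truncation_radius = 3 * sigma) {
  if (!is_scalar_num(sigma) || sigma <= 0)
    stop_skullmark("invalid_config", "sigma must be a positive number")
  if (!is_scalar_num(peak) || peak <= 0)
    stop_skullmark("invalid_config", "peak must be a positive number")
  if (!is_scalar_num(truncation_radius) || truncation_radius < sigma)
    stop_skullmark("invalid_config", "truncation_radius must be >= sigma")
  structure(list(sigma = sigma, peak = peak,
                 truncation_radius = truncation_radius),
            class = "heatmap_config")
}

#' Render a single truncated Gaussian heatmap
#'
#' @param shape `(H, W)` grid size.
#' @param center `(row, col)` Gaussian mean, 0-based; may be sub-pixel and
#'   may lie outside the grid (only the in-grid tail is then written).
#' @param config A [heatmap_config()].
#' @return An `H x W` matrix with values in `[0, peak]`.
#' @export
make_gaussian_heatmap <- function(shape, center, config = heatmap_config()) {
  if (!inherits(config, "heatmap_config"))
    config <- do.call(heatmap_config, as.list(config))
  if (length(shape) < 2L || any(shape[1:2] < 1))
    stop_skullmark("invalid_config", "shape must be positive (H, W)")
  if (!all(is.finite(center)))
    stop_skullmark("invalid_config", "center must be finite")
  H <- shape[1L]; W <- shape[2L]
  out <- matrix(0, H, W)
  tr <- config$truncation_radius
  r0 <- max(0L, floor(center[1L] - tr)); r1 <- min(H - 1L, ceiling(center[1L] + tr))
  c0 <- max(0L, floor(center[2L] - tr)); c1 <- min(W - 1L, ceiling(center[2L] + tr))
  if (r0 > r1 || c0 > c1) return(out)
  rr <- seq.int(r0, r1); cc <- seq.int(c0, c1)
  d2 <- outer((rr - center[1L])^2, (cc - center[2L])^2, `+`)
  vals <- config$peak * exp(-d2 / (2 * config$sigma^2))
  vals[d2 > tr^2] <- 0
  out[rr + 1L, cc + 1L] <- vals
  out
}

#' Build the 2-channel heatmap label for a landmark pair
#'
#' Channel 1 is rendered from bregma, channel 2 from lambda, each through
#' [make_gaussian_heatmap()]; the channels are independent (no mixing even
#' when the discs overlap).
#'
#' @param shape `(H, W)` grid size.
#' @param landmarks A [landmark_set()] whose `frame` must match `frame`.
#' @param config A [heatmap_config()].
#' @param frame Frame the grid lives in (default `"net"`).
#' @return An `H x W x 2` array of class `heatmap_label` with the config
#'   attached as attribute `config`.
#' @export
make_label <- function(shape, landmarks, config = heatmap_config(),
                       frame = "net") {
  if (!inherits(landmarks, "landmark_set"))
    stop_skullmark("invalid_config", "landmarks must be a landmark_set")
  if (landmarks$frame != frame)
    stop_skullmark("frame", sprintf(
      "landmarks are in frame '%s' but the label grid is '%s'",
      landmarks$frame, frame))
  lab <- array(0, c(shape[1L], shape[2L], 2L))
  lab[, , 1L] <- make_gaussian_heatmap(shape, landmarks$bregma, config)
  lab[, , 2L] <- make_gaussian_heatmap(shape, landmarks$lambda, config)
  structure(lab, config = config, frame = frame, class = "heatmap_label")
}

#' Decode landmark coordinates from a 2-channel heatmap
#'
#' Per channel, returns the 0-based `(row, col)` of the maximum value.
#' Ties are broken deterministically by the smallest row-major index
#' (`row * W + col`).
#'
#' @param values An `H x W x 2` array (channel 1 bregma, channel 2 lambda).
#' @param frame Frame tag for the returned coordinates.
#' @return A [landmark_set()].
#' @export
decode_heatmap <- function(values, frame = "net") {
  d <- dim(values)
  if (is.null(d) || length(d) < 3L || any(d[1:2] < 1L) || d[3L] < 2L)
    stop_skullmark("invalid_input", "values must be a non-empty H x W x 2 array")
  if (!all(is.finite(values)))
    stop_skullmark("invalid_input", "heatmap values must be finite")
  amax <- function(m) {
    idx <- which(m == max(m))           # column-major linear indices
    r <- (idx - 1L) %% nrow(m)
    c <- (idx - 1L) %/% nrow(m)
    best <- which.min(r * ncol(m) + c)  # smallest row-major index
    c(r[best], c[best])
  }
  b <- amax(values[, , 1L]); l <- amax(values[, , 2L])
  # built directly (not via landmark_set()): decoded coordinates may
  # legitimately coincide, e.g. on a constant heatmap
  structure(list(bregma = as.numeric(b), lambda = as.numeric(l), frame = frame),
            class = "landmark_set")
}
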