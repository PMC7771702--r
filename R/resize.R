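# Separable image resizing via explicit row/column weight matrices.
# Area weighting is used for all downsampling (mean-preserving, no aliasing
# tuning knobs); bilinear is available for the optional heatmap-upscaling
# decode path.  Operates on H x W matrices or H x W x C arrays of doubles.

area_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo)
    j1 <- min(ceiling(hi), n_in)
    j <- seq.int(j0, j1 - 1)
    w <- pmin(hi, j + 1) - pmax(lo, j)
    W[i, j + 1] <- w / r
  }
  W
}

bilinear_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    p <- (i - 0.5) * r - 0.5          # pixel-centre position in input
    j <- clamp(floor(p), 0, n_in - 1)
    f <- clamp(p - j, 0, 1)
    W[i, j + 1] <- W[i, j + 1] + (1 - f)
    jj <- min(j + 1, n_in - 1)
    W[i, jj + 1] <- W[i, jj + 1] + f
  }
  W
}

resize_matrix <- function(x, out_shape, method = c("area", "bilinear")) {
  method <- match.arg(method)
  wfun <- if (method == "area") area_weights else bilinear_weights
  Wr <- wfun(nrow(x), out_shape[1L])
  Wc <- wfun(ncol(x), out_shape[2L])
  Wr %*% x %*% t(Wc)
}

resize_image <- function(img, out_shape, method = "area") {
  if (is.matrix(img)) return(resize_matrix(img, out_shape, method))
  d <- dim(img)
  out <- array(0, c(out_shape[1L], out_shape[2L], d[3L]))
  for (ch in seq_len(d[3L]))
    out[, , ch] <- resize_matrix(img[, , ch], out_shape, method)
  out
}

# Extract a size x size window with top-left at `origin` (0-based, may
# extend beyond the image); out-of-range pixels are edge-replicated.
extract_window <- function(img, origin, size) {
  d <- dim(img)
  ri <- clamp(origin[1L] + seq_len(size) - 1, 0, d[1L] - 1) + 1
  ci <- clamp(origin[2L] + seq_len(size) - 1, 0, d[2L] - 1) + 1
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}
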