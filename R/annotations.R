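# Annotation-file IO and label export.

ann_columns <- c("image_path", "bbox_row0", "bbox_col0", "bbox_row1",
                 "bbox_col1", "bregma_row", "bregma_col", "lambda_row",
                 "lambda_col")

#' Read an annotation CSV
#'
#' Annotations carry, per image, the skull bounding box and the expert
#' bregma/lambda coordinates, all 0-based in the full-resolution frame
#' (bbox upper edges exclusive).
#'
#' @param path CSV path with columns `image_path`, `bbox_row0`,
#'   `bbox_col0`, `bbox_row1`, `bbox_col1`, `bregma_row`, `bregma_col`,
#'   `lambda_row`, `lambda_col` (extra columns such as `split` are kept).
#' @return A data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(ann_columns, names(ann))
  if (length(miss))
    stop_skullmark("invalid_input",
                   paste("annotation file lacks columns:",
                         paste(miss, collapse = ", ")))
  ann
}

#' Write an annotation CSV
#'
#' @param ann Data frame with at least the columns listed in
#'   [read_annotations()].
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  miss <- setdiff(ann_columns, names(ann))
  if (length(miss))
    stop_skullmark("invalid_input",
                   paste("annotation frame lacks columns:",
                         paste(miss, collapse = ", ")))
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

ann_landmarks <- function(row, frame = "full") {
  landmark_set(c(row$bregma_row, row$bregma_col),
               c(row$lambda_row, row$lambda_col), frame = frame)
}

ann_bbox <- function(row) {
  c(row$bbox_row0, row$bbox_col0, row$bbox_row1, row$bbox_col1)
}

#' Persist a heatmap label
#'
#' Writes the 2-channel label as a 32-bit float TIFF; for `format = "png"`
#' a third all-zero channel is appended so the label can be previewed as
#' an ordinary image.
#'
#' @param label An `H x W x 2` heatmap array (values in `[0, peak]`).
#' @param path Output path.
#' @param format `"tiff"` (exact) or `"png"` (8-bit preview).
#' @export
write_label <- function(label, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  lab <- unclass(label)
  if (format == "tiff") {
    tiff::writeTIFF(lab, path, bits.per.sample = 32L,
                    reduce = FALSE)
  } else {
    peak <- max(lab, 1e-12)
    preview <- array(0, c(dim(lab)[1:2], 3L))
    preview[, , 1:2] <- clamp(lab / peak, 0, 1)
    png::writePNG(preview, path)
  }
  invisible(path)
}

#' Read a heatmap label written by [write_label()]
#'
#' @param path TIFF path.
#' @return An `H x W x 2` array.
#' @export
read_label <- function(path) {
  # 2-sample float TIFFs make libtiff warn about the photometric tag
  lab <- suppressWarnings(tiff::readTIFF(path))
  lab[, , 1:2, drop = FALSE]
}
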