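#' Pipeline presets
#'
#' A preset bundles the resolution constants of the pipeline: canvas size,
#' the integer factor for the detection (low-resolution) frame, the crop
#' and network input sizes, the heatmap standard deviation in net-frame
#' pixels, and the FCN width multiplier.
#'
#' `"full"` matches the study conditions: 2448 x 3264 photographs,
#' 4x detection downsampling (612 x 816), a 640 crop mapped to a 256
#' network input (scale 2.5), sigma 20 and full network width.  `"tiny"`
#' scales every length by 4 (612 x 816 canvas, 160 crop, 64 net input,
#' sigma 5, width 1/4) while keeping the crop/net scale at 2.5; it exists
#' so that training-based checks run at desk scale.
#'
#' @param name `"full"` or `"tiny"`.
#' @return A list of class `skull_preset`.
#' @export
skull_preset <- function(name = c("full", "tiny")) {
  name <- match.arg(name)
  p <- switch(name,
    full = list(canvas = c(2448L, 3264L), lowres_factor = 4L,
                crop_size = 640L, net_size = 256L, sigma = 20,
                width_multiplier = 1,
                bl_distance_range = c(140, 190)),
    tiny = list(canvas = c(612L, 816L), lowres_factor = 4L,
                crop_size = 160L, net_size = 64L, sigma = 5,
                width_multiplier = 0.25,
                bl_distance_range = c(35, 47.5))
  )
  p$name <- name
  p$scale <- p$crop_size / 640        # length scale relative to the full preset
  structure(p, class = "skull_preset")
}
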