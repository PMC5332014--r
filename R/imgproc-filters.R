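#' Circular-kernel median filter
#'
#' Replaces each pixel by the median over a circular neighborhood
#' (`dx^2 + dy^2 <= radius^2`); image borders are handled by nearest-pixel
#' extension. Used on the nuclear channel (radius 2) to suppress noise and
#' smooth nuclear contours before watershed separation.
#'
#' @param image numeric matrix.
#' @param radius_px neighborhood radius in pixels (>= 1).
#' @return filtered matrix of the same shape and attributes.
#' @export
median_filter <- function(image, radius_px = 2) {
  stopifnot(is.matrix(image))
  if (!is.numeric(radius_px) || radius_px < 1) {
    abort("`radius_px` must be >= 1.", class = "wpb_parameter_error")
  }
  out <- cpp_median_filter(unclass_matrix(image), as.integer(radius_px))
  copy_image_attrs(out, image)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background surface and subtracts it, clamping at 0.
#' With `sliding_paraboloid = TRUE` (the default, and the variant used on the
#' WPB channel with radius 1) the background is the envelope obtained by
#' sliding a paraboloid of curvature `1/(2 * radius)` under the intensity
#' profile along rows, columns and both diagonal directions in turn; each 1-D
#' pass is a grayscale opening with a parabolic structuring element. With
#' `sliding_paraboloid = FALSE` a grayscale opening with a flat disc of the
#' given radius is used instead.
#'
#' @param image numeric matrix.
#' @param ball_radius_px ball radius in pixels (>= 1).
#' @param sliding_paraboloid use the sliding-paraboloid background estimator.
#' @return background-subtracted matrix (minimum 0), same shape.
#' @export
subtract_background <- function(image, ball_radius_px = 1, sliding_paraboloid = TRUE) {
  stopifnot(is.matrix(image))
  if (!is.numeric(ball_radius_px) || ball_radius_px < 1) {
    abort("`ball_radius_px` must be >= 1.", class = "wpb_parameter_error")
  }
  x <- unclass_matrix(image)
  if (sliding_paraboloid) {
    bg <- cpp_paraboloid_background(x, as.numeric(ball_radius_px))
  } else {
    brush <- EBImage::makeBrush(2L * as.integer(ball_radius_px) + 1L, shape = "disc")
    bg <- EBImage::imageData(EBImage::dilate(EBImage::erode(EBImage::Image(x), brush), brush))
  }
  out <- pmax(x - bg, 0)
  dim(out) <- dim(x)
  copy_image_attrs(out, image)
}

#' Bernsen local thresholding
#'
#' Local binarization on the 8-bit scale. For each pixel, the maximum and
#' minimum over a circular window (clipped at the borders) give
#' `contrast = max - min` and `midgray = (max + min) / 2`. Low-contrast
#' windows (`contrast < contrast_threshold`) are classified wholesale:
#' foreground iff `midgray >= 128`. Otherwise a pixel is foreground iff its
#' value `>= midgray`. The contrast threshold (default 15) is the single
#' sensitivity tunable of the WPB segmentation; raise it to 30 or 50 for weak
#' stainings where the default picks up out-of-focus background.
#'
#' @param image8 numeric matrix on the 0--255 scale (see [to_8bit()]).
#' @param window_radius_px circular window radius in pixels (default 15, the
#'   reference plugin's default).
#' @param contrast_threshold minimum local contrast, in 0--255.
#' @return logical matrix (TRUE = foreground).
#' @export
bernsen_threshold <- function(image8, window_radius_px = 15, contrast_threshold = 15) {
  stopifnot(is.matrix(image8))
  if (contrast_threshold < 0 || contrast_threshold > 255) {
    abort("`contrast_threshold` must lie in [0, 255].", class = "wpb_parameter_error")
  }
  if (max(image8) > 255 || min(image8) < 0) {
    abort("`image8` must be on the 8-bit scale [0, 255]; see to_8bit().",
          class = "wpb_parameter_error")
  }
  cpp_bernsen(unclass_matrix(image8), as.integer(window_radius_px),
              as.numeric(contrast_threshold))
}

# strip field_image class/attrs down to a plain numeric matrix
unclass_matrix <- function(x) {
  y <- as.numeric(x)
  dim(y) <- dim(x)
  y
}

copy_image_attrs <- function(out, src) {
  for (a in c("pixel_size_um", "bit_depth", "plate", "well", "field", "channel")) {
    attr(out, a) <- attr(src, a)
  }
  class(out) <- class(src)
  out
}
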