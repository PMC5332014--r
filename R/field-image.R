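#' Field images and label maps
#'
#' Images are plain numeric matrices indexed `[row, col]`, with pixel centers
#' at integer coordinates: pixel `(r, c)` (1-based in R) sits at
#' `(y, x) = (r - 1, c - 1)` in the 0-based, row-major convention used for all
#' reported coordinates. Intensities are 12-bit values (0--4095) stored in
#' 16-bit containers on disk. A `field_image` is such a matrix carrying its
#' pixel size and identity as attributes; all functions also accept plain
#' matrices.
#'
#' @param x numeric matrix of intensities.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param bit_depth nominal bit depth of the intensity scale.
#' @param plate,well,field,channel optional identity metadata.
#' @return `field_image()` returns the matrix with class `field_image` and
#'   metadata attributes.
#' @export
field_image <- function(x, pixel_size_um = 0.1615, bit_depth = 12,
                        plate = NA_character_, well = NA_character_,
                        field = NA_integer_, channel = NA_integer_) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  structure(x,
    pixel_size_um = pixel_size_um, bit_depth = bit_depth,
    plate = plate, well = well, field = field, channel = channel,
    class = c("field_image", class(matrix())))
}

#' @rdname field_image
#' @export
pixel_size <- function(x, default = 0.1615) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) default else ps
}

#' @param default pixel size used when `x` carries none.
#' @rdname field_image
#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, %.4f um/px, %d-bit",
              nrow(x), ncol(x), pixel_size(x), attr(x, "bit_depth") %||% 12L))
  id <- c(plate = attr(x, "plate"), well = attr(x, "well"))
  id <- id[!is.na(id)]
  if (length(id)) cat(" [", paste(names(id), id, sep = "=", collapse = " "), "]")
  cat("\n  range:", paste(signif(range(x), 5), collapse = " - "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum number of object labels encodable at a given bit depth
#'
#' Grey-shade labeling stores object identifiers as pixel values: an n-bit
#' raster has `2^n` distinct grey shades, and one shade (0) is reserved for
#' the background / separating mesh, leaving `2^n - 1` usable object labels
#' (255 at 8 bit, 65535 at 16 bit).
#'
#' @param bits integer bit depth (e.g. 8 or 16).
#' @param shades if `TRUE`, return the number of grey shades `2^bits` instead
#'   of the object-label capacity `2^bits - 1`.
#' @return integer count.
#' @export
label_capacity <- function(bits, shades = FALSE) {
  stopifnot(is.numeric(bits), bits >= 1, bits <= 31)
  n <- as.integer(2^bits)
  if (shades) n else n - 1L
}

# internal: raise the standard capacity error
capacity_error <- function(n, capacity, what = "labels") {
  abort(
    sprintf("label capacity exceeded: %d %s cannot be encoded (capacity %d with 0 reserved for background)",
            n, what, capacity),
    class = "wpb_capacity_error")
}

#' Convert a 12-bit image to the 8-bit scale
#'
#' Fixed linear mapping 0--4095 to 0--255 (rounded to nearest), independent of
#' the image content, so thresholding behaves identically across fields.
#'
#' @param image numeric matrix on the 12-bit scale.
#' @param max_value full-scale input value (default 4095).
#' @return numeric matrix with values in 0--255.
#' @export
to_8bit <- function(image, max_value = 4095) {
  stopifnot(is.matrix(image))
  round(pmin(pmax(image, 0), max_value) * 255 / max_value)
}
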