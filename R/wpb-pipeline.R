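#' Segment WPB objects on the vWF channel
#'
#' Works on a copy so intensity features can later be measured on the
#' original, unmodified image: rolling-ball background subtraction (radius 1,
#' sliding paraboloid), fixed 12-to-8-bit conversion, Bernsen local threshold
#' (circular window radius 15 px, contrast threshold from `config`), deletion
#' of all mask pixels lying on the Voronoi mesh (so no object ever crosses an
#' approximated cell boundary), 8-connected labeling, and removal of objects
#' larger than 10 um^2 (virtually merged WPB clumps unresolvable by the
#' optics).
#'
#' @param wpb_image numeric matrix (12-bit scale), the raw vWF channel.
#' @param zones influence-zone matrix from [influence_zones()] (0 = mesh).
#' @param config a [pipeline_config()]; `bernsen_contrast` is the single
#'   sensitivity tunable (default 15; use 30 or 50 for weak signal).
#' @return integer label matrix of WPB objects.
#' @export
segment_wpbs <- function(wpb_image, zones, config = pipeline_config()) {
  stopifnot(is.matrix(wpb_image))
  if (!all(dim(wpb_image) == dim(zones))) {
    abort("`wpb_image` and `zones` must have the same shape.", class = "wpb_parameter_error")
  }
  work <- subtract_background(wpb_image, config$rolling_ball_radius_px,
                              sliding_paraboloid = TRUE)
  work8 <- to_8bit(work, max_value = 2^(attr(wpb_image, "bit_depth") %||% 12) - 1)
  mask <- bernsen_threshold(work8, config$bernsen_window_radius_px, config$bernsen_contrast)
  mask[zones == 0L] <- FALSE          # WPB pixels overlapping the mesh are deleted
  labels <- label_components(mask, bits = 16)
  size_filter(labels, NULL, config$wpb_max_area_um2, config$pixel_size_um)
}

#' Extract the per-object WPB feature table
#'
#' Applies [measure_objects()] to the segmented WPB labels using the
#' *original* (unsubtracted) intensities and attaches plate/well/field
#' identifiers plus the `Label` string `"<well>_f<field>"` used by the
#' deposited result tables.
#'
#' @param wpb_labels integer label matrix from [segment_wpbs()].
#' @param original_image raw vWF channel, same shape.
#' @param plate,well,field identifiers attached to every row.
#' @param config a [pipeline_config()].
#' @return tibble: `Label`, `plate`, `well`, `field`, then the 24 feature
#'   columns of [measure_objects()] (empty but fully typed when no objects).
#' @export
extract_wpb_features <- function(wpb_labels, original_image, plate = "P1",
                                 well = "A01", field = 1L,
                                 config = pipeline_config()) {
  if (!all(dim(wpb_labels) == dim(original_image))) {
    abort("`wpb_labels` and `original_image` must have the same shape.",
          class = "wpb_parameter_error")
  }
  feats <- measure_objects(wpb_labels, original_image,
                           pixel_size_um = config$pixel_size_um,
                           slice = as.integer(field))
  dplyr::bind_cols(
    tibble(Label = rep(sprintf("%s_f%d", well, as.integer(field)), nrow(feats)),
           plate = rep(as.character(plate), nrow(feats)),
           well = rep(as.character(well), nrow(feats)),
           field = rep(as.integer(field), nrow(feats))),
    feats)
}

#' Assign each WPB object to its cell (influence zone)
#'
#' The cell identifier of an object is the mean of the zone-raster values over
#' the object's pixels. Because mesh pixels were deleted during segmentation,
#' every object lies inside exactly one zone and the mean is an exact
#' integer; a non-integer mean indicates that mesh deletion failed and raises
#' an integrity error.
#'
#' @param wpb_labels integer label matrix from [segment_wpbs()].
#' @param zones influence-zone matrix.
#' @param tol tolerance on integer-ness of the mean.
#' @return tibble with `object` and `cell_id`, one row per object (row count
#'   equals the feature-table row count by construction).
#' @export
assign_wpb_cell_ids <- function(wpb_labels, zones, tol = 1e-9) {
  stopifnot(all(dim(wpb_labels) == dim(zones)))
  n <- max(wpb_labels)
  if (n == 0) return(tibble(object = integer(), cell_id = integer()))
  fg <- which(wpb_labels > 0L)
  lab <- wpb_labels[fg]
  zv <- as.numeric(zones[fg])
  grp <- factor(lab, levels = seq_len(n))
  mean_zone <- as.numeric(rowsum(zv, grp)) / tabulate(lab, nbins = n)
  cell <- round(mean_zone)
  if (any(abs(mean_zone - cell) > tol) || any(cell < 1)) {
    abort("assign_wpb_cell_ids: object(s) span multiple zones or the mesh; mesh deletion failed",
          class = "wpb_integrity_error")
  }
  tibble(object = seq_len(n), cell_id = as.integer(cell))
}

#' Render a red-contour QC overlay
#'
#' Draws the 1-px outer contours of the segmented objects in red over the
#' grayscale image, the standard visual check for segmentation quality.
#'
#' @param image numeric matrix (grayscale base).
#' @param labels integer label matrix.
#' @param max_value full-scale intensity used to normalize the base image.
#' @return numeric array `c(nrow, ncol, 3)` with values in 0--1 (RGB).
#' @export
render_qc_overlay <- function(image, labels, max_value = 4095) {
  stopifnot(all(dim(image) == dim(labels)))
  base <- pmin(pmax(unclass_matrix(image) / max_value, 0), 1)
  rgb <- array(rep(base, 3), dim = c(nrow(image), ncol(image), 3))
  contour <- object_contours(labels)
  rgb[, , 1][contour] <- 1
  rgb[, , 2][contour] <- 0
  rgb[, , 3][contour] <- 0
  rgb
}

# boundary pixels of labeled objects: any 4-neighbor differs (background,
# another label, or the image border)
object_contours <- function(labels) {
  n <- max(labels)
  if (n == 0) return(matrix(FALSE, nrow(labels), ncol(labels)))
  exposed_edges_per_label(labels, n)$boundary
}
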