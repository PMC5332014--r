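#' Segment nuclei on the Hoechst channel
#'
#' Median filter (2 px circular radius) to suppress noise and smooth the
#' nuclear contours, Otsu global threshold, hole filling, distance-transform
#' watershed to separate touching nuclei, 8-connected labeling, and an area
#' gate of 50--2500 um^2 discarding specks and staining clumps that cannot be
#' nuclei.
#'
#' @param nuclei_image numeric matrix (12-bit scale).
#' @param config a [pipeline_config()].
#' @return list with `labels` (integer label matrix) and `nuclei`, a tibble
#'   with one row per surviving nucleus: `label`, `x`, `y` (centroid, px,
#'   0-based), `area_um2`. Zero surviving nuclei yields an empty tibble (the
#'   condition is signalled as a warning; downstream per-well statistics for
#'   such fields are undefined and excluded).
#' @export
segment_nuclei <- function(nuclei_image, config = pipeline_config()) {
  stopifnot(is.matrix(nuclei_image))
  ps <- config$pixel_size_um
  filt <- median_filter(nuclei_image, config$median_radius_px)
  full <- 2^(attr(nuclei_image, "bit_depth") %||% 12) - 1
  thr <- if (max(filt) > min(filt)) {
    EBImage::otsu(EBImage::Image(unclass_matrix(filt) / full),
                  range = c(0, 1), levels = full + 1) * full
  } else Inf
  mask <- unclass_matrix(filt) > thr
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  mask <- watershed_split(mask, smooth_sigma = config$watershed_sigma,
                          max_radius = config$watershed_max_radius)
  labels <- label_components(mask)
  labels <- size_filter(labels, config$nucleus_area_bounds_um2[1],
                        config$nucleus_area_bounds_um2[2], ps)
  nuclei <- nucleus_table(labels, ps)
  if (nrow(nuclei) == 0) {
    warn("segment_nuclei: no surviving nuclei in field; downstream well statistics undefined")
  }
  list(labels = labels, nuclei = nuclei)
}

nucleus_table <- function(labels, pixel_size_um) {
  n <- max(labels)
  if (n == 0) {
    return(tibble(label = integer(), x = numeric(), y = numeric(), area_um2 = numeric()))
  }
  fg <- which(labels > 0L)
  lab <- labels[fg]
  nr <- nrow(labels)
  x <- as.numeric((fg - 1L) %/% nr)
  y <- as.numeric((fg - 1L) %% nr)
  grp <- factor(lab, levels = seq_len(n))
  npx <- tabulate(lab, nbins = n)
  tibble(
    label = seq_len(n),
    x = as.numeric(rowsum(x, grp)) / npx,
    y = as.numeric(rowsum(y, grp)) / npx,
    area_um2 = npx * pixel_size_um^2)
}

#' Voronoi influence zones around nucleus centroids
#'
#' Approximates single-cell territories in a confluent monolayer: every pixel
#' is assigned to the nearest nucleus centroid (Euclidean distance on pixel
#' centers; ties go to the lower nucleus label), then a 1-px-wide separating
#' mesh (value 0) is drawn along zone boundaries on the higher-label side of
#' each 4-neighbor boundary. Labels are grey-shade encoded with 16-bit
#' capacity: at most 65535 zones, 0 reserved for the mesh.
#'
#' @param nuclei a nucleus tibble (`segment_nuclei()$nuclei`) or a two-column
#'   matrix/data frame of centroid `x`, `y` pixel coordinates (0-based).
#' @param shape integer `c(rows, cols)` of the raster.
#' @return integer matrix of zone labels with 0 for the mesh. With a single
#'   nucleus the whole raster is one zone and no mesh is drawn.
#' @export
influence_zones <- function(nuclei, shape) {
  if (is.data.frame(nuclei)) {
    cx <- nuclei$x; cy <- nuclei$y
  } else {
    nuclei <- as.matrix(nuclei)
    cx <- nuclei[, 1]; cy <- nuclei[, 2]
  }
  if (length(cx) < 1) abort("influence_zones requires at least one nucleus.", class = "wpb_parameter_error")
  if (length(cx) > label_capacity(16)) {
    capacity_error(length(cx), label_capacity(16), "zones")
  }
  zones <- cpp_nearest_centroid(as.integer(shape[1]), as.integer(shape[2]),
                                as.numeric(cy), as.numeric(cx))
  # 8-neighborhood convention: after mesh deletion no two pixels of different
  # zones remain 8-adjacent, so objects can never straddle zones by diagonal
  # contact around the mesh
  mesh <- boundary_side_mask(zones, connectivity = 8L)
  zones[mesh] <- 0L
  zones
}

#' Assign segmented nuclei to influence zones
#'
#' Mirrors the grey-shade measurement step of the screening workflow: the
#' zone identifier of a nucleus is the mean of the zone-raster values over the
#' nucleus's pixels, which is an exact integer when the nucleus lies inside a
#' single zone. A nucleus straddling the mesh (mean off an integer by more
#' than `tol`) is flagged and assigned the majority zone among its non-mesh
#' pixels, with a warning.
#'
#' @param nucleus_labels integer label matrix of nuclei.
#' @param zones influence-zone matrix from [influence_zones()].
#' @param tol tolerance on the deviation of the mean from an integer.
#' @return tibble with `label`, `zone`, `mean_zone_value`, `flagged`.
#' @export
assign_nuclei_to_zones <- function(nucleus_labels, zones, tol = 1e-6) {
  stopifnot(all(dim(nucleus_labels) == dim(zones)))
  n <- max(nucleus_labels)
  if (n == 0) {
    return(tibble(label = integer(), zone = integer(),
                  mean_zone_value = numeric(), flagged = logical()))
  }
  fg <- which(nucleus_labels > 0L)
  lab <- nucleus_labels[fg]
  zv <- zones[fg]
  grp <- factor(lab, levels = seq_len(n))
  npx <- tabulate(lab, nbins = n)
  mean_zone <- as.numeric(rowsum(as.numeric(zv), grp)) / npx
  zone <- as.integer(round(mean_zone))
  flagged <- abs(mean_zone - zone) > tol
  if (any(flagged)) {
    for (i in which(flagged)) {
      vals <- zv[lab == i & zv > 0L]
      zone[i] <- if (length(vals)) as.integer(names(which.max(table(vals)))) else 0L
    }
    warn(sprintf("assign_nuclei_to_zones: %d nucleus/nuclei straddle the mesh; majority zone assigned",
                 sum(flagged)))
  }
  tibble(label = seq_len(n), zone = zone, mean_zone_value = mean_zone, flagged = flagged)
}
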