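#' Watershed splitting of touching convex blobs
#'
#' Computes the Euclidean distance transform of the foreground, smooths it
#' with a Gaussian (sigma 1 px by default) so minor contour concavities do not
#' seed spurious basins, runs a watershed from the regional maxima (detected
#' within a `max_radius`-pixel neighborhood), and erases the watershed lines:
#' every foreground pixel whose 8-neighborhood contains a lower-numbered
#' watershed region is set to background, so the resulting binary mask has
#' 1-px-wide cuts and touching blobs become separate 8-connected components.
#'
#' @param mask logical matrix.
#' @param smooth_sigma Gaussian sigma (px) applied to the distance map.
#' @param max_radius neighborhood radius (px) used for regional-maximum
#'   detection (minimum seed separation).
#' @param tolerance minimum basin depth (in distance-map units) for a
#'   separate object.
#' @return logical matrix with separating cuts set to `FALSE`.
#' @export
watershed_split <- function(mask, smooth_sigma = 1, max_radius = 5, tolerance = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(mask)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  if (smooth_sigma > 0) dm <- EBImage::gblur(dm, sigma = smooth_sigma)
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance, ext = max_radius))
  storage.mode(ws) <- "integer"
  ws[mask & ws == 0L] <- max(ws) + 1L  # pixels the watershed left unassigned
  cut <- boundary_side_mask(ws, connectivity = 8L)
  out <- mask & ws > 0L & !cut
  out
}

# TRUE for labeled pixels having a lower-numbered positive label in their
# neighborhood: the deterministic "higher-label side" on which separating
# lines / mesh pixels are drawn, keeping them exactly 1 px wide.
boundary_side_mask <- function(labels, connectivity = 4L) {
  nr <- nrow(labels); nc <- ncol(labels)
  shift <- function(m, dr, dc) {
    # value of the neighbor at offset (dr, dc); 0 outside the raster
    out <- matrix(0L, nr, nc)
    rd <- seq_len(nr - abs(dr)); cd <- seq_len(nc - abs(dc))
    out[rd + max(0L, -dr), cd + max(0L, -dc)] <-
      m[rd + max(0L, dr), cd + max(0L, dc), drop = FALSE]
    out
  }
  offs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  res <- matrix(FALSE, nr, nc)
  for (o in offs) {
    nb <- shift(labels, o[1], o[2])
    res <- res | (labels > 0L & nb > 0L & nb < labels)
  }
  res
}

#' Label connected components
#'
#' 8-connected components are labeled 1..N in raster-scan (row-major) order of
#' each component's first pixel; 0 is background. When `bits` is given, the
#' labeler enforces the grey-shade encoding capacity (`2^bits - 1` labels, 0
#' reserved) and raises a capacity error beyond it.
#'
#' @param mask logical matrix.
#' @param bits optional raster bit depth limiting the number of encodable
#'   labels (see [label_capacity()]).
#' @return integer matrix of labels (a label map).
#' @export
label_components <- function(mask, bits = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- cpp_label8(mask)
  if (!is.null(bits)) {
    n <- max(lab)
    cap <- label_capacity(bits)
    if (n > cap) capacity_error(n, cap, "components")
  }
  lab
}

#' Remove objects outside an area range
#'
#' Components whose calibrated area (`pixel count * pixel_size_um^2`) falls
#' outside `[min_area_um2, max_area_um2]` are erased; either bound may be
#' `NULL` (open). Survivors are renumbered 1..N preserving label order. Used
#' with bounds `[50, 2500]` on nuclei (artefact specks / staining clumps) and
#' `(NULL, 10]` on WPB objects, where anything above 10 um^2 is treated as a
#' virtually merged WPB clump the optics could not resolve.
#'
#' @param labels integer label matrix.
#' @param min_area_um2,max_area_um2 inclusive area bounds in um^2 (or `NULL`).
#' @param pixel_size_um pixel size in um/px.
#' @return relabeled integer matrix.
#' @export
size_filter <- function(labels, min_area_um2 = NULL, max_area_um2 = NULL,
                        pixel_size_um = 0.1615) {
  stopifnot(is.matrix(labels))
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.", class = "wpb_parameter_error")
  if (!is.null(min_area_um2) && !is.null(max_area_um2) && min_area_um2 > max_area_um2) {
    abort("`min_area_um2` must not exceed `max_area_um2`.", class = "wpb_parameter_error")
  }
  n <- max(labels)
  if (n == 0) return(labels)
  area <- tabulate(labels[labels > 0L], nbins = n) * pixel_size_um^2
  keep <- rep(TRUE, n)
  if (!is.null(min_area_um2)) keep <- keep & area >= min_area_um2
  if (!is.null(max_area_um2)) keep <- keep & area <= max_area_um2
  newlab <- integer(n)
  newlab[keep] <- seq_len(sum(keep))
  out <- labels
  fg <- labels > 0L
  out[fg] <- newlab[labels[fg]]
  out
}
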