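#' Per-object morphometry and intensity features
#'
#' Measures, for every labeled object, the 24 features of the screening
#' workflow: calibrated area, intensity statistics from the *raw* image
#' (mean, SD, min, max, median, integrated densities), centroid, perimeter of
#' the pixel-corner boundary polygon, best-fit ellipse (major/minor axis and
#' angle, from second central moments rescaled so the ellipse area equals the
#' object area), circularity (capped at 1), Feret and minimum Feret diameters
#' by rotating calipers over the convex hull of the pixel-corner points, the
#' Feret endpoint coordinates and angle, aspect ratio, roundness (1/AR) and
#' solidity.
#'
#' Geometry conventions: pixel centers at integer 0-based coordinates
#' (x = column, y = row); outlines and hulls are built on pixel corners
#' (center +/- 0.5); areas are pixel counts times `pixel_size_um^2`. Lengths
#' (Area, Perim, Major, Minor, Feret, MinFeret) are calibrated to micrometres;
#' X, Y, FeretX, FeretY are in pixels. Of the two endpoints of the Feret
#' diameter, the one with the smaller x (then smaller y) is reported.
#' Angles are degrees in [0, 180), measured counterclockwise from the image
#' x-axis with y pointing up (image rows point down).
#'
#' @param labels integer label matrix (labels 1..N, 0 background).
#' @param intensity numeric matrix of raw intensities, same shape.
#' @param pixel_size_um pixel size in um/px.
#' @param slice stack index recorded in the `Slice` column.
#' @return a tibble with one row per object, columns in the screen's feature
#'   table order: Area, Mean, StdDev, Min, Max, X, Y, Perim, Major, Minor,
#'   Angle, Circ, Feret, IntDen, Median, RawIntDen, Slice, FeretX, FeretY,
#'   FeretAngle, MinFeret, AR, Round, Solidity.
#' @export
measure_objects <- function(labels, intensity, pixel_size_um = 0.1615, slice = 1L) {
  stopifnot(is.matrix(labels), is.matrix(intensity))
  if (!all(dim(labels) == dim(intensity))) {
    abort("`labels` and `intensity` must have the same shape.", class = "wpb_parameter_error")
  }
  ps <- pixel_size_um
  n <- max(labels)
  if (n == 0) return(empty_feature_tibble())

  fg <- which(labels > 0L)
  lab <- labels[fg]
  vals <- intensity[fg]
  nr <- nrow(labels)
  r0 <- (fg - 1L) %% nr          # 0-based row = y
  c0 <- (fg - 1L) %/% nr         # 0-based col = x
  x <- as.numeric(c0); y <- as.numeric(r0)

  grp <- factor(lab, levels = seq_len(n))
  npx <- tabulate(lab, nbins = n)
  s1 <- as.numeric(rowsum(vals, grp))
  sx <- as.numeric(rowsum(x, grp)); sy <- as.numeric(rowsum(y, grp))
  sxx <- as.numeric(rowsum(x * x, grp)); syy <- as.numeric(rowsum(y * y, grp))
  sxy <- as.numeric(rowsum(x * y, grp))
  svv <- as.numeric(rowsum(vals * vals, grp))

  mean_v <- s1 / npx
  sd_v <- ifelse(npx > 1, sqrt(pmax(svv - npx * mean_v^2, 0) / (npx - 1)), 0)
  sp <- split(vals, grp)
  min_v <- unname(vapply(sp, min, numeric(1)))
  max_v <- unname(vapply(sp, max, numeric(1)))
  med_v <- unname(vapply(sp, median, numeric(1)))

  mx <- sx / npx; my <- sy / npx
  # second central moments of pixel centers; +1/12 is the variance of the
  # unit-square pixel footprint, keeping 1-px-thin objects non-degenerate
  vxx <- sxx / npx - mx^2 + 1 / 12
  vyy <- syy / npx - my^2 + 1 / 12
  vxy <- sxy / npx - mx * my
  half_tr <- (vxx + vyy) / 2
  disc <- sqrt(pmax((vxx - vyy)^2 / 4 + vxy^2, 0))
  l1 <- pmax(half_tr + disc, 0); l2 <- pmax(half_tr - disc, 0)
  a0 <- 4 * sqrt(l1); b0 <- 4 * sqrt(l2)   # unscaled full axes (px)
  scale <- sqrt(4 * npx / (pi * a0 * b0))
  major_px <- a0 * scale; minor_px <- b0 * scale
  ex <- ifelse(abs(vxy) > 1e-12, vxy, ifelse(vxx >= vyy, 1, 0))
  ey <- ifelse(abs(vxy) > 1e-12, l1 - vxx, ifelse(vxx >= vyy, 0, 1))
  angle <- (atan2(-ey, ex) * 180 / pi) %% 180

  # perimeter: exposed pixel edges (4-neighborhood, image border counts)
  expo <- exposed_edges_per_label(labels, n)
  perim_px <- expo$edges
  boundary <- expo$boundary

  feret <- matrix(NA_real_, n, 6)  # feret_px, minferet_px, fx, fy, fangle, hull_area
  bmask <- boundary[fg]
  bx <- split(x[bmask], grp[bmask])
  by <- split(y[bmask], grp[bmask])
  for (i in seq_len(n)) {
    feret[i, ] <- feret_from_pixels(bx[[i]], by[[i]])
  }

  area_um2 <- npx * ps^2
  perim_um <- perim_px * ps
  circ <- pmin(1, 4 * pi * npx / perim_px^2)

  tibble(
    Area = area_um2, Mean = mean_v, StdDev = sd_v, Min = min_v, Max = max_v,
    X = mx, Y = my, Perim = perim_um,
    Major = major_px * ps, Minor = minor_px * ps, Angle = angle, Circ = circ,
    Feret = feret[, 1] * ps, IntDen = area_um2 * mean_v, Median = med_v,
    RawIntDen = s1, Slice = as.integer(slice),
    FeretX = feret[, 3], FeretY = feret[, 4], FeretAngle = feret[, 5],
    MinFeret = feret[, 2] * ps,
    AR = major_px / minor_px, Round = minor_px / major_px,
    Solidity = pmin(1, npx / feret[, 6]))
}

empty_feature_tibble <- function() {
  tibble(
    Area = numeric(), Mean = numeric(), StdDev = numeric(), Min = numeric(),
    Max = numeric(), X = numeric(), Y = numeric(), Perim = numeric(),
    Major = numeric(), Minor = numeric(), Angle = numeric(), Circ = numeric(),
    Feret = numeric(), IntDen = numeric(), Median = numeric(),
    RawIntDen = numeric(), Slice = integer(), FeretX = numeric(),
    FeretY = numeric(), FeretAngle = numeric(), MinFeret = numeric(),
    AR = numeric(), Round = numeric(), Solidity = numeric())
}

# Count exposed (object/background or object/other-object) pixel edges per
# label over the 4-neighborhood, and flag boundary pixels.  The exposed-edge
# count is the length of the pixel-corner boundary polygon in pixel units.
exposed_edges_per_label <- function(labels, n) {
  nr <- nrow(labels); nc <- ncol(labels)
  fgm <- labels > 0L
  edges <- numeric(n)
  boundary <- matrix(FALSE, nr, nc)
  pad_shift <- function(dr, dc) {
    out <- matrix(0L, nr, nc)
    rd <- seq_len(nr - abs(dr)); cd <- seq_len(nc - abs(dc))
    out[rd + max(0L, -dr), cd + max(0L, -dc)] <-
      labels[rd + max(0L, dr), cd + max(0L, dc), drop = FALSE]
    out
  }
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad_shift(o[1], o[2])
    ex <- fgm & (nb != labels)
    boundary <- boundary | ex
    idx <- which(ex)
    if (length(idx)) {
      tab <- tabulate(labels[idx], nbins = n)
      edges <- edges + tab
    }
  }
  list(edges = edges, boundary = boundary)
}

# Feret geometry of one object from its boundary-pixel centers (0-based).
# Builds the convex hull of the 4 corner points of each boundary pixel, takes
# the maximum pairwise hull distance (Feret) with its endpoints, and the
# rotating-calipers minimum width over hull edges (MinFeret).
feret_from_pixels <- function(px, py) {
  cx <- c(px - 0.5, px + 0.5, px - 0.5, px + 0.5)
  cy <- c(py - 0.5, py - 0.5, py + 0.5, py + 0.5)
  h <- grDevices::chull(cx, cy)
  hx <- cx[h]; hy <- cy[h]
  m <- length(hx)
  if (m == 1) return(c(0, 0, hx, hy, 0, 1e-9))
  dx <- outer(hx, hx, "-"); dy <- outer(hy, hy, "-")
  d2 <- dx^2 + dy^2
  k <- which.max(d2)
  i <- (k - 1) %% m + 1; j <- (k - 1) %/% m + 1
  feret <- sqrt(d2[k])
  # report the endpoint with smaller x (then smaller y)
  if (hx[i] < hx[j] || (hx[i] == hx[j] && hy[i] <= hy[j])) { a <- i; b <- j } else { a <- j; b <- i }
  fangle <- (atan2(-(hy[b] - hy[a]), hx[b] - hx[a]) * 180 / pi) %% 180
  # rotating calipers: minimum width is attained perpendicular to a hull edge
  minf <- Inf
  for (e in seq_len(m)) {
    e2 <- if (e == m) 1L else e + 1L
    ux <- hx[e2] - hx[e]; uy <- hy[e2] - hy[e]
    len <- sqrt(ux^2 + uy^2)
    if (len < 1e-12) next
    w <- max(abs((hx - hx[e]) * (-uy / len) + (hy - hy[e]) * (ux / len)))
    if (w < minf) minf <- w
  }
  if (!is.finite(minf)) minf <- 0
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  c(feret, minf, hx[a], hy[a], fangle, max(hull_area, 1e-9))
}
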