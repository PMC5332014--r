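#' Specification of a synthetic field of view
#'
#' Describes one synthetic field emulating a confluent endothelial monolayer
#' imaged at high content: elliptical nuclei at near-confluent density and
#' rod-shaped WPBs (rectangles with semicircular caps) scattered inside each
#' cell's Voronoi territory, over a sloped background with additive Gaussian
#' noise, on the 12-bit intensity scale.
#'
#' Defaults emulate the screening conditions: 0.1615 um pixels, a 688 x 512 px
#' field (~9200 um^2) holding ~16 cells -- about 70--100 cells over a well's
#' five fields of view -- with ~60 WPBs per cell, rod lengths log-normal
#' around 1.4 um, and rod intensity an order of magnitude above background.
#'
#' @param image_shape integer `c(rows, cols)` in pixels.
#' @param pixel_size_um pixel size, um/px.
#' @param n_nuclei number of nuclei placed in the field.
#' @param nucleus_axes_um list with `major` and `minor` ranges (full axis
#'   diameters, um) sampled uniformly per nucleus.
#' @param touching_fraction fraction of nuclei placed as deliberately touching
#'   partners (exercises watershed separation).
#' @param nucleus_intensity peak added intensity of a nucleus.
#' @param wpb_per_cell Poisson mean WPB count per cell.
#' @param wpb_length_um list `meanlog`, `sdlog` of the log-normal rod length
#'   (total length including caps, um).
#' @param wpb_min_length_um lower truncation of rod length (um); never below
#'   `wpb_width_um`.
#' @param wpb_width_um rod width (um).
#' @param wpb_clearance_px placement clearance in pixels: every rod keeps at
#'   least this distance from its cell's territory boundary (WPBs are
#'   perinuclear organelles, not membrane-apposed) and from other rods (the
#'   generator renders resolvable objects; unresolvable clumps are exercised
#'   separately by the clump-filter fixtures).
#' @param wpb_intensity added intensity of a rod (uniform along the rod).
#' @param background numeric `c(offset, slope_x, slope_y)`: additive plane
#'   `offset + slope_x * x + slope_y * y` (per-pixel slopes), shared by both
#'   channels.
#' @param noise_sigma SD of additive Gaussian noise (clipped to 0--4095).
#' @param seed RNG seed; identical (spec, seed) pairs give bit-identical
#'   output.
#' @return a list of class `field_spec`.
#' @export
field_spec <- function(image_shape = c(512, 688), pixel_size_um = 0.1615,
                       n_nuclei = 16,
                       nucleus_axes_um = list(major = c(9.5, 11.5), minor = c(7.5, 9)),
                       touching_fraction = 0.1,
                       nucleus_intensity = 2000,
                       wpb_per_cell = 60,
                       wpb_length_um = list(meanlog = log(1.4), sdlog = 0.5),
                       wpb_min_length_um = 0.4,
                       wpb_width_um = 0.4,
                       wpb_clearance_px = 2,
                       wpb_intensity = 1200,
                       background = c(offset = 100, slope_x = 0.03, slope_y = 0.02),
                       noise_sigma = 8, seed = 1L) {
  spec <- list(
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    n_nuclei = as.integer(n_nuclei), nucleus_axes_um = nucleus_axes_um,
    touching_fraction = touching_fraction,
    nucleus_intensity = nucleus_intensity,
    wpb_per_cell = wpb_per_cell, wpb_length_um = wpb_length_um,
    wpb_min_length_um = max(wpb_min_length_um, wpb_width_um),
    wpb_width_um = wpb_width_um, wpb_clearance_px = wpb_clearance_px,
    wpb_intensity = wpb_intensity,
    background = background, noise_sigma = noise_sigma, seed = as.integer(seed))
  class(spec) <- "field_spec"
  validate_field_spec(spec)
  spec
}

validate_field_spec <- function(spec) {
  geom <- c(spec$image_shape, spec$pixel_size_um,
            unlist(spec$nucleus_axes_um), spec$wpb_width_um,
            spec$wpb_length_um$sdlog)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    abort("field_spec: all geometric parameters must be strictly positive.",
          class = "wpb_parameter_error")
  }
  ints <- c(spec$nucleus_intensity, spec$wpb_intensity, spec$background[["offset"]])
  if (any(ints < 0) || any(ints > 4095)) {
    abort("field_spec: intensities must lie in [0, 4095].", class = "wpb_parameter_error")
  }
  if (spec$n_nuclei < 0 || spec$wpb_per_cell < 0 || spec$noise_sigma < 0 ||
      spec$wpb_clearance_px < 0 ||
      spec$touching_fraction < 0 || spec$touching_fraction > 1) {
    abort("field_spec: counts, noise and fractions must be non-negative (fraction <= 1).",
          class = "wpb_parameter_error")
  }
  invisible(spec)
}

# mean coverage of each whole pixel by the analytic shape, computed on an
# s-fold supersampled grid and box-downsampled (s = 4)
downsample_block <- function(m, s) {
  nrb <- nrow(m) / s; ncb <- ncol(m) / s
  a <- array(m, c(s, nrb, s * ncb))
  a <- colSums(a)                       # nrb x (s*ncb)
  a <- array(t(a), c(s, ncb, nrb))
  t(colSums(a)) / s^2                   # nrb x ncb
}

# anti-aliased pixel coverage of a shape over its bounding box;
# inside_fun(xs, ys) -> logical matrix over the supersampled grid
# (xs along columns, ys along rows, 0-based px).  The caller adds
# `value * cov` into the image in place.
shape_coverage <- function(nr, nc, x0, y0, half_extent, inside_fun, s = 4L) {
  r1 <- max(1L, floor(y0 - half_extent) + 1L); r2 <- min(nr, ceiling(y0 + half_extent) + 1L)
  c1 <- max(1L, floor(x0 - half_extent) + 1L); c2 <- min(nc, ceiling(x0 + half_extent) + 1L)
  if (r1 > r2 || c1 > c2) return(NULL)
  sub <- (seq_len(s) - 0.5) / s - 0.5
  ys <- as.vector(t(outer(r1:r2 - 1, sub, "+")))
  xs <- as.vector(t(outer(c1:c2 - 1, sub, "+")))
  inside <- inside_fun(matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE),
                       matrix(ys, nrow = length(ys), ncol = length(xs)))
  cov <- downsample_block(inside * 1, s)
  list(coverage_sum = sum(cov), box = c(r1, r2, c1, c2), cov = cov)
}


# squared distance from each pixel center (rows0 x cols0 grid, 0-based) to
# the rod's spine segment
segment_dist2 <- function(x0, y0, theta, len_px, width_px, rows0, cols0) {
  half_spine <- max((len_px - width_px) / 2, 0)
  ex <- cos(theta) * half_spine; ey <- sin(theta) * half_spine
  ax <- x0 - ex; ay <- y0 - ey
  vx <- 2 * ex; vy <- 2 * ey
  vv <- vx^2 + vy^2
  nry <- length(rows0); ncx <- length(cols0)
  X <- matrix(cols0, nry, ncx, byrow = TRUE)
  Y <- matrix(rows0, nry, ncx)
  if (vv < 1e-12) {
    (X - ax)^2 + (Y - ay)^2
  } else {
    t <- pmin(pmax(((X - ax) * vx + (Y - ay) * vy) / vv, 0), 1)
    (X - (ax + t * vx))^2 + (Y - (ay + t * vy))^2
  }
}

rod_inside_fun <- function(x0, y0, theta, len_px, width_px) {
  half_spine <- max((len_px - width_px) / 2, 0)
  ex <- cos(theta) * half_spine; ey <- sin(theta) * half_spine
  ax <- x0 - ex; ay <- y0 - ey; bx <- x0 + ex; by <- y0 + ey
  r2 <- (width_px / 2)^2
  function(xs, ys) {
    vx <- bx - ax; vy <- by - ay
    vv <- vx^2 + vy^2
    if (vv < 1e-12) {
      (xs - ax)^2 + (ys - ay)^2 <= r2
    } else {
      t <- pmin(pmax(((xs - ax) * vx + (ys - ay) * vy) / vv, 0), 1)
      (xs - (ax + t * vx))^2 + (ys - (ay + t * vy))^2 <= r2
    }
  }
}

ellipse_inside_fun <- function(x0, y0, theta, a_px, b_px) {
  ct <- cos(theta); st <- sin(theta)
  function(xs, ys) {
    dx <- xs - x0; dy <- ys - y0
    u <- (dx * ct + dy * st) / a_px
    v <- (-dx * st + dy * ct) / b_px
    u^2 + v^2 <= 1
  }
}

#' Generate one synthetic field with ground truth
#'
#' Places nuclei by rejection sampling (pairwise center separation at least
#' 0.9 times the sum of the mean radii, so grazing contact is possible but
#' deep merges are not, plus a configurable fraction of deliberately
#' touching partners), draws per-cell WPB counts from a Poisson
#' distribution, places each rod inside its cell's Voronoi territory with
#' the configured clearance to the boundary and to other rods (rejection; rods
#' that cannot be placed are dropped from both image and truth), renders all
#' shapes at 4x supersampling with box downsampling, adds the background
#' plane and Gaussian noise, and rounds to integer 12-bit values.
#'
#' @param spec a [field_spec()].
#' @param max_attempts_per_nucleus rejection-sampling budget per nucleus.
#' @return list with `nuclei_image` and `wpb_image` ([field_image()]s) and
#'   `truth`: a list with tibbles `nuclei` (cell, x/y centroid um and px,
#'   axes, area) and `wpbs` (cell, centroid, true length/width/area,
#'   rendered pixel area, added integrated intensity), the vector
#'   `per_cell_counts`, and `wpb_mask`, the logical raster of rendered rod
#'   coverage > 0.
#' @export
generate_field <- function(spec, max_attempts_per_nucleus = 200L) {
  validate_field_spec(spec)
  withr::with_seed(spec$seed, generate_field_impl(spec, max_attempts_per_nucleus))
}

generate_field_impl <- function(spec, max_attempts) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size_um
  bgp <- spec$background
  xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
  bg <- bgp[["offset"]] + bgp[["slope_x"]] * xg + bgp[["slope_y"]] * yg
  nuc_img <- bg
  wpb_img <- bg
  wpb_cov <- matrix(0, nr, nc)

  n <- spec$n_nuclei
  empty_truth <- list(
    nuclei = tibble(cell = integer(), x_um = numeric(), y_um = numeric(),
                    x_px = numeric(), y_px = numeric(),
                    major_um = numeric(), minor_um = numeric(),
                    theta = numeric(), area_um2 = numeric()),
    wpbs = tibble(cell = integer(), x_um = numeric(), y_um = numeric(),
                  length_um = numeric(), width_um = numeric(),
                  area_um2 = numeric(), rendered_area_px = numeric(),
                  total_intensity = numeric()),
    per_cell_counts = integer(), wpb_mask = matrix(FALSE, nr, nc))

  finish <- function(truth) {
    if (spec$noise_sigma > 0) {
      nuc_img <- nuc_img + rnorm(nr * nc, 0, spec$noise_sigma)
      wpb_img <- wpb_img + rnorm(nr * nc, 0, spec$noise_sigma)
    }
    mk <- function(m, channel) {
      field_image(round(pmin(pmax(m, 0), 4095)), pixel_size_um = ps, channel = channel)
    }
    list(nuclei_image = mk(nuc_img, 1L), wpb_image = mk(wpb_img, 2L), truth = truth)
  }

  if (n == 0) return(finish(empty_truth))

  # --- nuclei placement ---------------------------------------------------
  maj <- runif(n, spec$nucleus_axes_um$major[1], spec$nucleus_axes_um$major[2]) / ps
  mnr <- runif(n, spec$nucleus_axes_um$minor[1], spec$nucleus_axes_um$minor[2]) / ps
  th <- runif(n, 0, pi)
  reff <- (maj + mnr) / 4
  n_touch <- floor(spec$touching_fraction * n / 2)
  n_seed <- n - n_touch
  margin <- max(maj) / 2 + 1
  cxs <- numeric(0); cys <- numeric(0)
  attempts <- 0L
  budget <- max_attempts * n
  for (i in seq_len(n_seed)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > budget) {
        abort(sprintf("generate_field: could not place nucleus %d of %d after %d attempts; nucleus density too high for the field",
                      i, n, budget), class = "wpb_placement_error")
      }
      px <- runif(1, margin, nc - 1 - margin)
      py <- runif(1, margin, nr - 1 - margin)
      if (length(cxs)) {
        # mean-radius separation: allows incidental near-touching but never
        # deep merges, so watershed can split every pair
        dmin <- 0.9 * (reff[seq_along(cxs)] + reff[i])
        if (any((cxs - px)^2 + (cys - py)^2 < dmin^2)) next
      }
      cxs <- c(cxs, px); cys <- c(cys, py)
      break
    }
  }
  # touching partners placed next to the first n_touch seeds
  for (k in seq_len(n_touch)) {
    i <- n_seed + k
    placed <- FALSE
    for (try in seq_len(400L)) {
      anchor <- sample.int(n_seed, 1L)
      ang <- runif(1, 0, 2 * pi)
      d <- 0.95 * (mnr[anchor] + mnr[i]) / 2
      px <- cxs[anchor] + d * cos(ang); py <- cys[anchor] + d * sin(ang)
      if (px < margin || px > nc - 1 - margin || py < margin || py > nr - 1 - margin) next
      others <- setdiff(seq_along(cxs), anchor)
      if (length(others)) {
        dmin <- 0.9 * (reff[others] + reff[i])
        if (any((cxs[others] - px)^2 + (cys[others] - py)^2 < dmin^2)) next
      }
      cxs <- c(cxs, px); cys <- c(cys, py)
      placed <- TRUE
      break
    }
    if (!placed) {
      abort("generate_field: could not place touching nucleus; nucleus density too high for the field",
            class = "wpb_placement_error")
    }
  }

  nuc_area_px <- numeric(n)
  for (i in seq_len(n)) {
    res <- shape_coverage(nr, nc, cxs[i], cys[i], maj[i] / 2 + 1,
                          ellipse_inside_fun(cxs[i], cys[i], th[i], maj[i] / 2, mnr[i] / 2))
    box <- res$box
    nuc_img[box[1]:box[2], box[3]:box[4]] <-
      nuc_img[box[1]:box[2], box[3]:box[4]] + spec$nucleus_intensity * res$cov
    nuc_area_px[i] <- res$coverage_sum
  }
  truth_nuclei <- tibble(
    cell = seq_len(n), x_um = cxs * ps, y_um = cys * ps,
    x_px = cxs, y_px = cys, major_um = maj * ps, minor_um = mnr * ps,
    theta = th, area_um2 = nuc_area_px * ps^2)

  # --- WPB placement within Voronoi territories ---------------------------
  zmap <- cpp_nearest_centroid(nr, nc, cys, cxs)
  counts_drawn <- rpois(n, spec$wpb_per_cell)
  width_px <- spec$wpb_width_um / ps
  clear_px <- spec$wpb_clearance_px
  occ <- matrix(FALSE, nr, nc)   # pixels claimed by placed rods
  rod_rec <- matrix(NA_real_, sum(counts_drawn), 8)
  ri <- 0L
  placed_counts <- integer(n)
  zone_idx <- split(seq_len(nr * nc), factor(zmap, levels = seq_len(n)))
  for (cell in seq_len(n)) {
    k <- counts_drawn[cell]
    if (k == 0) next
    len_um <- rlnorm(k, spec$wpb_length_um$meanlog, spec$wpb_length_um$sdlog)
    len_um <- pmax(len_um, spec$wpb_min_length_um)
    pool <- zone_idx[[cell]]
    if (!length(pool)) next
    for (j in seq_len(k)) {
      L <- len_um[j] / ps
      for (try in seq_len(40L)) {
        pix <- pool[sample.int(length(pool), 1L)]
        x0 <- (pix - 1L) %/% nr + runif(1, -0.5, 0.5)
        y0 <- (pix - 1L) %% nr + runif(1, -0.5, 0.5)
        theta <- runif(1, 0, pi)
        half <- L / 2 + width_px / 2 + clear_px + 1
        if (x0 - half < 0 || x0 + half > nc - 1 || y0 - half < 0 || y0 + half > nr - 1) next
        # clearance-fattened footprint must stay inside the territory and
        # off previously placed rods
        r1 <- floor(y0 - half) + 1L; r2 <- ceiling(y0 + half) + 1L
        c1 <- floor(x0 - half) + 1L; c2 <- ceiling(x0 + half) + 1L
        d2 <- segment_dist2(x0, y0, theta, L, width_px, r1:r2 - 1, c1:c2 - 1)
        fat <- d2 <= (width_px / 2 + clear_px)^2
        core <- d2 <= (width_px / 2 + 0.71)^2
        zsub <- zmap[r1:r2, c1:c2, drop = FALSE]
        if (any(fat & zsub != cell)) next
        if (any(fat & occ[r1:r2, c1:c2])) next
        res <- shape_coverage(nr, nc, x0, y0, half,
                              rod_inside_fun(x0, y0, theta, L, width_px))
        box <- res$box
        wpb_img[box[1]:box[2], box[3]:box[4]] <-
          wpb_img[box[1]:box[2], box[3]:box[4]] + spec$wpb_intensity * res$cov
        wpb_cov[box[1]:box[2], box[3]:box[4]] <-
          wpb_cov[box[1]:box[2], box[3]:box[4]] + res$cov
        occ[r1:r2, c1:c2] <- occ[r1:r2, c1:c2] | core
        ri <- ri + 1L
        geom_area <- (len_um[j] - spec$wpb_width_um) * spec$wpb_width_um +
          pi * (spec$wpb_width_um / 2)^2
        rod_rec[ri, ] <- c(cell, x0 * ps, y0 * ps, len_um[j], spec$wpb_width_um,
                           geom_area, res$coverage_sum,
                           spec$wpb_intensity * res$coverage_sum)
        placed_counts[cell] <- placed_counts[cell] + 1L
        break
      }
      # rods that cannot be placed are dropped (dense territories)
    }
  }
  truth_wpbs <- if (ri) {
    rr <- rod_rec[seq_len(ri), , drop = FALSE]
    tibble(cell = as.integer(rr[, 1]), x_um = rr[, 2], y_um = rr[, 3],
           length_um = rr[, 4], width_um = rr[, 5], area_um2 = rr[, 6],
           rendered_area_px = rr[, 7], total_intensity = rr[, 8])
  } else empty_truth$wpbs
  truth <- list(nuclei = truth_nuclei, wpbs = truth_wpbs,
                per_cell_counts = placed_counts, wpb_mask = wpb_cov > 0)
  finish(truth)
}
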