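# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own algorithms: direct rule evaluation, exhaustive
# search, flood fill, long-run iteration.

# Bernsen rule evaluated directly per pixel over the circular window
oracle_bernsen <- function(img, radius, ct) {
  nr <- nrow(img); nc <- ncol(img)
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  out <- matrix(NA, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + off$dy; cc <- c + off$dx
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    vals <- img[cbind(rr[ok], cc[ok])]
    mx <- max(vals); mn <- min(vals); mid <- (mx + mn) / 2
    out[r, c] <- if (mx - mn < ct) mid >= 128 else img[r, c] >= mid
  }
  out
}

# all pixel-corner points of a label's pixels (0-based centers)
corner_points <- function(labels, lab) {
  idx <- which(labels == lab)
  nr <- nrow(labels)
  x <- (idx - 1) %/% nr; y <- (idx - 1) %% nr
  cbind(x = c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
        y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}

# Feret by exhaustive max pairwise distance over ALL corner points
oracle_feret <- function(pts) {
  d <- as.matrix(dist(pts))
  max(d)
}

# MinFeret by dense caliper-angle sweep (upper bound approaching the truth)
oracle_minferet <- function(pts, n_angles = 1800) {
  best <- Inf
  for (a in seq(0, pi, length.out = n_angles)) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    best <- min(best, max(proj) - min(proj))
  }
  best
}

# nearest-centroid assignment via which.min (first minimum = lowest label)
oracle_voronoi <- function(nrow, ncol, cy, cx) {
  out <- matrix(0L, nrow, ncol)
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    d <- (r - 1 - cy)^2 + (c - 1 - cx)^2
    out[r, c] <- which.min(d)
  }
  out
}

# 8-connected labeling by plain flood fill, raster-scan label order
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        rr <- p[1] + dy; cc <- p[2] + dx
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# random connected-ish blob label map for morphometry property tests
random_blob <- function(n = 60, nr = 32, nc = 32, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, nr, nc)
    r <- sample(8:(nr - 8), 1); c <- sample(8:(nc - 8), 1)
    m[r, c] <- TRUE
    for (i in seq_len(n)) {
      idx <- which(m)
      p <- idx[sample.int(length(idx), 1)]
      pr <- (p - 1) %% nr + 1; pc <- (p - 1) %/% nr + 1
      rr <- min(max(pr + sample(-1:1, 1), 2), nr - 1)
      cc <- min(max(pc + sample(-1:1, 1), 2), nc - 1)
      m[rr, cc] <- TRUE
    }
    m
  })
}

# greedy one-to-one centroid matching of truth rods to measured objects;
# returns per-truth-object Feret error (um), NA when unmatched
match_feret_errors <- function(truth, feats, pixel_size_um, max_dist_um = 0.5) {
  used <- rep(FALSE, nrow(feats))
  err <- rep(NA_real_, nrow(truth))
  if (!nrow(feats)) return(err)
  mx <- feats$X * pixel_size_um; my <- feats$Y * pixel_size_um
  for (i in seq_len(nrow(truth))) {
    d <- (mx - truth$x_um[i])^2 + (my - truth$y_um[i])^2
    j <- which.min(d)
    if (d[j] < max_dist_um^2 && !used[j]) {
      used[j] <- TRUE
      err[i] <- feats$Feret[j] - truth$length_um[i]
    }
  }
  err
}

# run the single-field image pipeline on a generated field
run_field_pipeline <- function(fld, config = pipeline_config()) {
  seg <- suppressWarnings(segment_nuclei(fld$nuclei_image, config))
  zones <- influence_zones(seg$nuclei, dim(fld$nuclei_image))
  wl <- segment_wpbs(unclass(fld$wpb_image), zones, config)
  ft <- extract_wpb_features(wl, unclass(fld$wpb_image), config = config)
  list(seg = seg, zones = zones, labels = wl, features = ft)
}
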