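render_ellipse_img <- function(nr, nc, cy, cx, a, b, value = 2000, bg = 100) {
  img <- matrix(bg, nr, nc)
  inside <- outer(seq_len(nr) - 1, seq_len(nc) - 1,
                  function(y, x) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
  img[inside] <- bg + value
  img
}

test_that("well-separated nuclei are all recovered; size gate removes specks", {
  fld <- generate_field(field_spec(n_nuclei = 12, wpb_per_cell = 0,
                                   touching_fraction = 0, seed = 5))
  seg <- segment_nuclei(fld$nuclei_image)
  expect_equal(nrow(seg$nuclei), 12)
  expect_true(all(seg$nuclei$area_um2 >= 50 & seg$nuclei$area_um2 <= 2500))
  # centroids near truth
  tr <- fld$truth$nuclei
  for (i in seq_len(12)) {
    d <- sqrt((seg$nuclei$x - tr$x_px[i])^2 + (seg$nuclei$y - tr$y_px[i])^2)
    expect_lt(min(d), 2)
  }

  # one 30 um^2 speck + one ~120 um^2 ellipse -> 1 nucleus
  ps <- 0.1615
  img <- render_ellipse_img(200, 200, 60, 60, sqrt(120 / pi) / ps * 0.98,
                            sqrt(120 / pi) / ps * 0.98 * 1.02)
  speck_r <- sqrt(30 / pi) / ps
  sp <- outer(seq_len(200) - 1, seq_len(200) - 1,
              function(y, x) ((x - 150)^2 + (y - 150)^2) <= speck_r^2)
  img[sp] <- 2100
  seg2 <- segment_nuclei(img)
  expect_equal(nrow(seg2$nuclei), 1)
})

test_that("touching nuclei are separated by the watershed", {
  # two ellipses whose boundaries overlap slightly
  img <- render_ellipse_img(160, 220, 80, 70, 34, 25)
  img2 <- render_ellipse_img(160, 220, 80, 132, 34, 25)
  both <- pmax(img, img2)
  seg <- segment_nuclei(both)
  expect_equal(nrow(seg$nuclei), 2)
})

test_that("two-centroid zones split at the perpendicular bisector", {
  z <- influence_zones(data.frame(x = c(10, 30), y = c(10, 10)), c(20, 40))
  expect_equal(z[6, 6], 1L)    # (x=5, y=5)
  expect_equal(z[6, 36], 2L)   # (x=35, y=5)
  non_mesh <- z != 0
  xcoord <- matrix(rep(0:39, each = 20), 20, 40)
  expect_true(all(z[non_mesh & xcoord <= 19] == 1))
  expect_true(all(z[non_mesh & xcoord >= 21] == 2))
})

test_that("single nucleus owns the whole raster with no mesh", {
  z <- influence_zones(data.frame(x = 5, y = 5), c(12, 15))
  expect_true(all(z == 1L))
})

test_that("zone labels equal brute-force nearest-centroid assignment", {
  for (i in 1:5) {
    k <- 3 + 4 * i
    cx <- withr::with_seed(i, runif(k, 0, 39))
    cy <- withr::with_seed(100 + i, runif(k, 0, 29))
    z <- influence_zones(data.frame(x = cx, y = cy), c(30, 40))
    o <- oracle_voronoi(30, 40, cy, cx)
    non_mesh <- z != 0
    expect_true(all(z[non_mesh] == o[non_mesh]))
    # partition: mesh + zones cover the raster exactly once
    expect_equal(sum(non_mesh) + sum(z == 0), 30 * 40)
    # each centroid pixel carries its own zone
    own <- z[cbind(round(cy) + 1, round(cx) + 1)]
    expect_true(all(own == seq_len(k) | own == 0))
  }
})

test_that("zone capacity is bounded by the 16-bit grey-shade encoding", {
  expect_equal(label_capacity(8, shades = TRUE), 256)
  expect_equal(label_capacity(16), 65535)
  pts <- data.frame(x = runif(65536, 0, 99), y = runif(65536, 0, 99))
  expect_error(influence_zones(pts, c(100, 100)), class = "wpb_capacity_error")
})

test_that("nuclei are assigned to their zones; straddlers get majority + warning", {
  # four well-separated nuclei: midlines stay far from every nucleus
  img <- matrix(100, 200, 260)
  for (ctr in list(c(50, 60), c(50, 200), c(150, 60), c(150, 200))) {
    inside <- outer(seq_len(200) - 1, seq_len(260) - 1,
                    function(y, x) ((x - ctr[2]) / 32)^2 + ((y - ctr[1]) / 24)^2 <= 1)
    img[inside] <- 2100
  }
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$nuclei), 4)
  zones <- influence_zones(seg$nuclei, dim(img))
  asg <- assign_nuclei_to_zones(seg$labels, zones)
  expect_equal(nrow(asg), 4)
  expect_false(any(asg$flagged))
  # bijection: each zone exactly one nucleus; zone of the centroid pixel
  expect_setequal(asg$zone, 1:4)
  ctr_zone <- zones[cbind(round(seg$nuclei$y) + 1, round(seg$nuclei$x) + 1)]
  expect_equal(asg$zone, ctr_zone)
  # constructed straddler: nucleus blob laid across the mesh
  z2 <- influence_zones(data.frame(x = c(10, 30), y = c(10, 10)), c(20, 40))
  lab <- matrix(0L, 20, 40); lab[8:12, 17:26] <- 1L
  expect_warning(asg2 <- assign_nuclei_to_zones(lab, z2), "straddle")
  expect_true(asg2$flagged[1])
  expect_true(asg2$zone[1] %in% 1:2)
})
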