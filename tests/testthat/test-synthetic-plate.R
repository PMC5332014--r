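test_that("empty spec yields constant-background images and empty truth", {
  sp <- field_spec(image_shape = c(40, 50), n_nuclei = 0, wpb_per_cell = 0,
                   background = c(offset = 100, slope_x = 0, slope_y = 0),
                   noise_sigma = 0, seed = 1)
  fld <- generate_field(sp)
  expect_true(all(fld$nuclei_image == 100))
  expect_true(all(fld$wpb_image == 100))
  expect_equal(nrow(fld$truth$nuclei), 0)
  expect_equal(nrow(fld$truth$wpbs), 0)
})

test_that("identical (spec, seed) pairs give bit-identical output", {
  sp <- field_spec(image_shape = c(192, 192), n_nuclei = 3, wpb_per_cell = 8,
                   seed = 7)
  a <- generate_field(sp)
  b <- generate_field(sp)
  expect_identical(a, b)
  sp2 <- sp; sp2$seed <- 8L
  expect_false(identical(generate_field(sp2)$wpb_image, a$wpb_image))
})

test_that("spec validation rejects bad geometry and intensities", {
  expect_error(field_spec(pixel_size_um = 0), class = "wpb_parameter_error")
  expect_error(field_spec(wpb_width_um = -1), class = "wpb_parameter_error")
  expect_error(field_spec(wpb_intensity = 5000), class = "wpb_parameter_error")
  expect_error(field_spec(noise_sigma = -1), class = "wpb_parameter_error")
  expect_error(field_spec(touching_fraction = 1.5), class = "wpb_parameter_error")
})

test_that("placement failure at infeasible density names density as cause", {
  sp <- field_spec(image_shape = c(120, 120), n_nuclei = 40, wpb_per_cell = 0,
                   seed = 1)
  expect_error(generate_field(sp, max_attempts_per_nucleus = 10),
               regexp = "density", class = "wpb_placement_error")
})

test_that("per-cell WPB counts follow the Poisson model (99% band)", {
  sp <- field_spec(n_nuclei = 20, wpb_per_cell = 10, seed = 1)
  fld <- generate_field(sp)
  total <- nrow(fld$truth$wpbs)
  band <- qpois(c(0.005, 0.995), 20 * 10)
  expect_gte(total, band[1])
  expect_lte(total, band[2])
  # truth bookkeeping invariants
  expect_equal(sum(fld$truth$per_cell_counts), total)
  expect_true(all(fld$truth$wpbs$cell %in% seq_len(20)))
})

test_that("rendered rod pixel areas agree with geometric truth areas", {
  fld <- generate_field(field_spec(seed = 3, noise_sigma = 0))
  tr <- fld$truth$wpbs
  ps <- 0.1615
  rel <- abs(tr$rendered_area_px * ps^2 - tr$area_um2) / tr$area_um2
  # anti-aliased coverage integrates the analytic area up to boundary
  # quantization of the 4x supersampled grid
  expect_lt(mean(rel), 0.05)
  expect_lt(max(rel), 0.20)
})

test_that("increasing wpb_intensity strictly increases foreground mean", {
  sp1 <- field_spec(image_shape = c(160, 160), n_nuclei = 4, wpb_per_cell = 15,
                    wpb_intensity = 600, seed = 5)
  sp2 <- sp1; sp2$wpb_intensity <- 1400
  a <- generate_field(sp1); b <- generate_field(sp2)
  m <- a$truth$wpb_mask
  expect_true(any(m))
  expect_lt(mean(a$wpb_image[m]), mean(b$wpb_image[m]))
})

test_that("plate generation applies per-well effects and is deterministic", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  sp <- field_spec(image_shape = c(160, 160), n_nuclei = 3, wpb_per_cell = 12,
                   seed = 11)
  layout <- screen_layout(fields_per_well = 1)
  wells <- c("A02", "B03", "A09", "B10")  # two samples, two positive controls
  t1 <- generate_plate(layout, sp, dir1, wells = wells)
  t2 <- generate_plate(layout, sp, dir2, wells = wells)
  expect_identical(t1$wpbs, t2$wpbs)
  f <- "A02_f1_ch2.tif"
  expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                   readBin(file.path(dir2, f), "raw", 1e6))
  cnt <- tapply(t1$wpbs$well, t1$wpbs$well, length)
  # count x0.1 in positive controls
  expect_lt(mean(cnt[c("A09", "B10")], na.rm = TRUE),
            0.35 * mean(cnt[c("A02", "B03")]))
})
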