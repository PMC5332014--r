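test_that("well ids parse strictly and round-trip", {
  expect_equal(parse_well_id("A01")$row, 0L)
  expect_equal(parse_well_id("A01")$col, 0L)
  expect_equal(parse_well_id("H12")$row, 7L)
  expect_equal(parse_well_id("H12")$col, 11L)
  expect_error(parse_well_id("I01"), class = "wpb_parse_error")
  expect_error(parse_well_id("A13"), class = "wpb_parse_error")
  expect_error(parse_well_id("a01"), class = "wpb_parse_error")
  expect_error(parse_well_id("A1"), class = "wpb_parse_error")
  all_wells <- plate_wells()
  idx <- parse_well_id(all_wells)
  expect_equal(well_id(idx$row, idx$col), all_wells)
})

test_that("pipeline config carries the workflow defaults and logs overrides", {
  cfg <- pipeline_config()
  expect_equal(cfg$median_radius_px, 2L)
  expect_equal(cfg$nucleus_area_bounds_um2, c(50, 2500))
  expect_equal(cfg$bernsen_window_radius_px, 15L)
  expect_equal(cfg$bernsen_contrast, 15)
  expect_equal(cfg$rolling_ball_radius_px, 1L)
  expect_equal(cfg$wpb_max_area_um2, 10)
  expect_equal(cfg$feret_cut_um, 1.5)
  expect_equal(cfg$z_threshold, 2)
  expect_equal(cfg$pixel_size_um, 0.1615)
  expect_message(pipeline_config(bernsen_contrast = 30), "overriding")
  expect_error(pipeline_config(not_a_knob = 1), class = "wpb_parameter_error")
})

test_that("TIFF round-trip preserves 12-bit values exactly", {
  img <- withr::with_seed(2, matrix(sample(0:4095, 80 * 60, TRUE), 80, 60))
  p <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(img, p)
  back <- read_field_tiff(p)
  expect_equal(unclass(back)[seq_along(img)], as.numeric(img), ignore_attr = TRUE)
})

test_that("manifest discovery validates channels and file naming", {
  d <- withr::local_tempdir()
  img <- matrix(100, 32, 32)
  for (w in c("A01", "A02")) for (f in 1:2) for (ch in 1:2) {
    write_field_tiff(img, file.path(d, sprintf("%s_f%d_ch%d.tif", w, f, ch)))
  }
  m <- plate_manifest(d)
  expect_equal(m$wells, c("A01", "A02"))
  expect_equal(m$fields_per_well, 2)
  expect_equal(nrow(m$files), 8)
  # remove one WPB channel image -> error naming the gap
  file.remove(file.path(d, "A02_f2_ch2.tif"))
  expect_error(plate_manifest(d), class = "wpb_input_error")
  expect_error(plate_manifest(file.path(d, "nope")), class = "wpb_input_error")
})

test_that("3-column screen files round-trip and reference manifest wells", {
  wf <- tibble::tibble(plate = "P1", well = c("A01", "B02"),
                       PercentWPBarea = c(0.5, 0.25),
                       TotalWPBnrPerCellNR = c(10, 20),
                       TotalWPBrawIntDenPerCellNR = c(1e5, 2e5),
                       TotalFoVpercentWPBnr = c(0.4, 0.6))
  d <- withr::local_tempdir()
  write_screen_inputs(wf, d)
  f <- file.path(d, "2_TotalWPBnrPerCellNR", "P1.txt")
  expect_true(file.exists(f))
  back <- read_screen_input(f)
  expect_equal(back$value, c(10, 20))
  expect_equal(back$well, wf$well)
  expect_true(all(back$well %in% wf$well))
})

test_that("run_plate processes a small plate end to end, deterministically", {
  d <- withr::local_tempdir()
  sp <- field_spec(image_shape = c(200, 200), n_nuclei = 3, wpb_per_cell = 25,
                   seed = 31)
  layout <- plate_layout(fields_per_well = 2)
  wells <- c("A01", "B05", "C07")
  truth <- generate_plate(layout, sp, d, plate_id = "T1", wells = wells)
  m <- plate_manifest(d, plate_id = "T1")
  out1 <- withr::local_tempdir()
  res <- run_plate(m, out_dir = out1)
  expect_s3_class(res, "plate_result")
  expect_equal(sort(unique(res$well_features$well)), wells)
  expect_equal(nrow(res$log), 6)
  expect_true(all(res$log$status == "ok"))
  # cell ids table row counts equal feature table row counts per field
  expect_equal(nrow(res$cell_ids), nrow(res$features))
  # well feature within reach of the generator truth (count per cell)
  tw <- truth$wells
  for (w in wells) {
    got <- res$well_features$TotalWPBnrPerCellNR[res$well_features$well == w]
    want <- tw$n_wpb[tw$well == w] / (2 * 3)   # fields * nuclei
    expect_lt(abs(got - want) / want, 0.15)
  }
  # deterministic rerun: byte-identical CSV outputs
  out2 <- withr::local_tempdir()
  run_plate(plate_manifest(d, plate_id = "T1"), out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  }
  # result CSVs re-read into equal tables
  ff <- utils::read.csv(file.path(out1, "T1_Results_Features.csv"))
  expect_equal(nrow(ff), nrow(res$features))
  expect_equal(ff$Feret, res$features$Feret, tolerance = 1e-12)
})

test_that("a whole default plate is 480 field pairs", {
  layout <- plate_layout(fields_per_well = 5)
  expect_equal(nrow(layout$wells) * layout$fields_per_well, 480)
  # generated on disk (down-scaled fields): one TIFF pair per field
  d <- withr::local_tempdir()
  sp <- field_spec(image_shape = c(96, 96), n_nuclei = 0, wpb_per_cell = 0,
                   noise_sigma = 2, seed = 1)
  generate_plate(layout, sp, d, plate_id = "P1")
  tifs <- list.files(d, pattern = "\\.tif$")
  expect_equal(length(tifs), 480 * 2)
  expect_equal(length(unique(sub("_ch[0-9]+\\.tif$", "", tifs))), 480)
})
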