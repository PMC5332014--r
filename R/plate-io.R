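#' Pipeline configuration
#'
#' All numeric parameters of the workflow with their screening defaults.
#' Any override of a default is reported with a message for auditability.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `pipeline_config` with fields: `median_radius_px`
#'   (2), `nucleus_area_bounds_um2` (c(50, 2500)), `bernsen_window_radius_px`
#'   (15), `bernsen_contrast` (15), `rolling_ball_radius_px` (1),
#'   `wpb_max_area_um2` (10), `feret_cut_um` (1.5), `z_threshold` (2),
#'   `pixel_size_um` (0.1615), `watershed_sigma` (1), `watershed_max_radius`
#'   (5), `cellcount_mode` ("zones" counts all influence zones; "legacy"
#'   counts only cells containing at least one WPB, mirroring extraction from
#'   the cell-ID tables), `seed` (1).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    median_radius_px = 2L,
    nucleus_area_bounds_um2 = c(50, 2500),
    bernsen_window_radius_px = 15L,
    bernsen_contrast = 15,
    rolling_ball_radius_px = 1L,
    wpb_max_area_um2 = 10,
    feret_cut_um = 1.5,
    z_threshold = 2,
    pixel_size_um = 0.1615,
    watershed_sigma = 1,
    watershed_max_radius = 5L,
    cellcount_mode = "zones",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste("pipeline_config: unknown parameter(s):", paste(unknown, collapse = ", ")),
          class = "wpb_parameter_error")
  }
  for (nm in names(over)) {
    message(sprintf("pipeline_config: overriding %s = %s", nm,
                    paste(format(over[[nm]]), collapse = ",")))
    defaults[[nm]] <- over[[nm]]
  }
  if (!defaults$cellcount_mode %in% c("zones", "legacy")) {
    abort("pipeline_config: cellcount_mode must be 'zones' or 'legacy'.",
          class = "wpb_parameter_error")
  }
  structure(defaults, class = "pipeline_config")
}

#' Read and write single-channel 16-bit TIFF fields
#'
#' Intensities are 12-bit values stored in 16-bit containers; values are
#' written and read back exactly.
#'
#' @param image numeric matrix of integers in 0..65535.
#' @param path file path.
#' @export
write_field_tiff <- function(image, path) {
  tiff::writeTIFF(unclass_matrix(image) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @param pixel_size_um pixel size recorded on the returned [field_image()].
#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path, pixel_size_um = 0.1615) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  field_image(x + 0, pixel_size_um = pixel_size_um)
}

#' Discover a plate's field images on disk
#'
#' Scans a plate directory for files named `<well>_f<field>_ch<channel>.tif`
#' and builds the manifest the pipeline runs from. The channel map assigns
#' channel indices to the two roles the analysis uses (`nuclei`, `wpb`);
#' both must be present for every (well, field).
#'
#' @param dir plate directory.
#' @param channels named integer vector mapping roles to channel indices.
#' @param pixel_size_um pixel size of the images.
#' @param plate_id plate identifier (defaults to the directory name).
#' @return list of class `plate_manifest`: `plate`, `dir`, `files` (tibble:
#'   well, field, channel, path), `channels`, `pixel_size_um`, `wells`,
#'   `fields_per_well`.
#' @export
plate_manifest <- function(dir, channels = c(nuclei = 1L, wpb = 2L),
                           pixel_size_um = 0.1615, plate_id = basename(dir)) {
  if (!dir.exists(dir)) abort(paste("plate_manifest: no such directory:", dir),
                              class = "wpb_input_error")
  if (!all(c("nuclei", "wpb") %in% names(channels))) {
    abort("plate_manifest: channel map must name `nuclei` and `wpb`.",
          class = "wpb_input_error")
  }
  fn <- list.files(dir, pattern = "^[A-H](0[1-9]|1[0-2])_f[0-9]+_ch[0-9]+\\.tif$")
  if (!length(fn)) abort(paste("plate_manifest: no field images found in", dir),
                         class = "wpb_input_error")
  m <- regmatches(fn, regexec("^([A-H][0-9]{2})_f([0-9]+)_ch([0-9]+)\\.tif$", fn))
  files <- tibble(
    well = vapply(m, `[`, "", 2),
    field = as.integer(vapply(m, `[`, "", 3)),
    channel = as.integer(vapply(m, `[`, "", 4)),
    path = file.path(dir, fn))
  need <- tidyr::expand_grid(
    dplyr::distinct(files[, c("well", "field")]),
    channel = unname(channels))
  have <- dplyr::semi_join(need, files, by = c("well", "field", "channel"))
  if (nrow(have) < nrow(need)) {
    miss <- dplyr::anti_join(need, files, by = c("well", "field", "channel"))
    abort(sprintf("plate_manifest: %d required channel image(s) missing (e.g. %s field %d channel %d)",
                  nrow(miss), miss$well[1], miss$field[1], miss$channel[1]),
          class = "wpb_input_error")
  }
  structure(list(
    plate = plate_id, dir = dir, files = files, channels = channels,
    pixel_size_um = pixel_size_um,
    wells = sort(unique(files$well)),
    fields_per_well = max(files$field)), class = "plate_manifest")
}

#' Run the full image pipeline on one plate
#'
#' For every (well, field): nucleus segmentation, Voronoi influence zones,
#' nucleus-to-zone assignment, WPB segmentation, per-object feature
#' extraction on the original intensities, and WPB-to-cell assignment; then
#' the four per-well statistics. Per-field failures are logged and skipped;
#' the plate fails only if every field fails.
#'
#' @param manifest a [plate_manifest()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory to write the plate's result CSVs
#'   (`<plate>_Results_Features.csv`, `<plate>_Results_Nuc_Features.csv`,
#'   `<plate>_Results_WBP_cell_ID.csv`, `<plate>_well_features.csv`).
#' @param overlays if `TRUE`, also write red-contour QC overlay PNGs.
#' @return list of class `plate_result`: `plate`, `well_features`,
#'   `features` (per-object), `nuc_features`, `cell_ids`, `cell_counts`,
#'   `log` (per-field status tibble).
#' @export
run_plate <- function(manifest, config = pipeline_config(), out_dir = NULL,
                      overlays = FALSE) {
  stopifnot(inherits(manifest, "plate_manifest"))
  ps <- manifest$pixel_size_um
  if (ps != config$pixel_size_um) {
    config$pixel_size_um <- ps
  }
  feats <- list(); nucs <- list(); ids <- list(); counts <- list(); logs <- list()
  pairs <- dplyr::distinct(manifest$files[, c("well", "field")])
  pairs <- pairs[order(pairs$well, pairs$field), ]
  for (i in seq_len(nrow(pairs))) {
    well <- pairs$well[i]; fld <- pairs$field[i]
    res <- tryCatch(
      run_field(manifest, well, fld, config, out_dir, overlays),
      error = function(e) e)
    if (inherits(res, "error")) {
      logs[[i]] <- tibble(well = well, field = fld, n_nuclei = NA_integer_,
                          n_wpbs = NA_integer_, status = "error",
                          message = conditionMessage(res))
      next
    }
    feats[[i]] <- res$features
    nucs[[i]] <- res$nuc_features
    ids[[i]] <- res$cell_ids
    counts[[i]] <- res$cell_count
    logs[[i]] <- tibble(well = well, field = fld,
                        n_nuclei = res$n_nuclei, n_wpbs = nrow(res$features),
                        status = "ok", message = "")
  }
  log <- dplyr::bind_rows(logs)
  if (all(log$status == "error")) {
    abort(sprintf("run_plate: all %d fields of plate %s failed; first error: %s",
                  nrow(log), manifest$plate, log$message[1]),
          class = "wpb_input_error")
  }
  features <- dplyr::bind_rows(feats)
  nuc_features <- dplyr::bind_rows(nucs)
  cell_ids <- dplyr::bind_rows(ids)
  cell_counts <- dplyr::bind_rows(counts)
  wf <- dplyr::bind_rows(lapply(sort(unique(cell_counts$well)), function(w) {
    dplyr::bind_cols(
      tibble(plate = manifest$plate, well = w),
      compute_well_features(features[features$well == w, , drop = FALSE],
                            cell_counts[cell_counts$well == w, , drop = FALSE],
                            feret_cut_um = config$feret_cut_um))
  }))
  out <- structure(list(
    plate = manifest$plate, well_features = wf, features = features,
    nuc_features = nuc_features, cell_ids = cell_ids,
    cell_counts = cell_counts, log = log), class = "plate_result")
  if (!is.null(out_dir)) write_plate_result(out, out_dir)
  out
}

run_field <- function(manifest, well, fld, config, out_dir = NULL, overlays = FALSE) {
  ps <- manifest$pixel_size_um
  pathof <- function(role) {
    ch <- manifest$channels[[role]]
    f <- manifest$files
    p <- f$path[f$well == well & f$field == fld & f$channel == ch]
    if (length(p) != 1) abort(sprintf("missing %s channel for %s field %d", role, well, fld),
                              class = "wpb_input_error")
    p
  }
  nuc_img <- read_field_tiff(pathof("nuclei"), ps)
  wpb_img <- read_field_tiff(pathof("wpb"), ps)
  seg <- segment_nuclei(nuc_img, config)
  n_nuclei <- nrow(seg$nuclei)
  if (n_nuclei == 0) {
    return(list(features = empty_field_features(manifest$plate, well, fld),
                nuc_features = tibble(), cell_ids = tibble(),
                cell_count = tibble(well = well, field = fld, n_cells = 0L),
                n_nuclei = 0L))
  }
  zones <- influence_zones(seg$nuclei, dim(nuc_img))
  # nuclei crossing the Voronoi midline are expected in confluent layers;
  # they are flagged in the returned table rather than warned per field
  assign <- suppressWarnings(assign_nuclei_to_zones(seg$labels, zones))
  nuc_features <- dplyr::bind_cols(
    tibble(Label = sprintf("%s_f%d", well, fld), plate = manifest$plate,
           well = well, field = fld),
    dplyr::rename(dplyr::left_join(seg$nuclei, assign, by = "label"),
                  Mean = "zone"))
  wl <- segment_wpbs(unclass_matrix(wpb_img), zones, config)
  features <- extract_wpb_features(wl, unclass_matrix(wpb_img),
                                   plate = manifest$plate, well = well,
                                   field = fld, config = config)
  cid <- assign_wpb_cell_ids(wl, zones)
  cell_ids <- dplyr::bind_cols(
    tibble(Label = rep(sprintf("%s_f%d", well, fld), nrow(cid)),
           plate = rep(manifest$plate, nrow(cid)),
           well = rep(well, nrow(cid)), field = rep(fld, nrow(cid))), cid)
  n_cells <- if (config$cellcount_mode == "zones") n_nuclei
             else length(unique(cid$cell_id))
  if (overlays && !is.null(out_dir) && requireNamespace("png", quietly = TRUE)) {
    dir.create(file.path(out_dir, "overlay_vWF_RGB"), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(render_qc_overlay(unclass_matrix(wpb_img), wl),
                  file.path(out_dir, "overlay_vWF_RGB",
                            sprintf("%s_%s_f%d.png", manifest$plate, well, fld)))
  }
  list(features = features, nuc_features = nuc_features, cell_ids = cell_ids,
       cell_count = tibble(well = well, field = fld, n_cells = as.integer(n_cells)),
       n_nuclei = n_nuclei)
}

empty_field_features <- function(plate, well, fld) {
  dplyr::bind_cols(
    tibble(Label = character(), plate = character(), well = character(),
           field = integer()),
    empty_feature_tibble())
}

write_plate_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, paste0(res$plate, "_", name, ".csv")),
                     row.names = FALSE)
  }
  w(res$features, "Results_Features")
  w(res$nuc_features, "Results_Nuc_Features")
  w(res$cell_ids, "Results_WBP_cell_ID")
  w(res$well_features, "well_features")
  invisible(out_dir)
}

#' Write / read the 3-column screen input format
#'
#' One tab-separated file per plate per feature, under a folder named after
#' the feature: plate identifier, well identifier (e.g. A01, H12), measured
#' value.
#'
#' @param well_features a `plate_result$well_features` tibble.
#' @param dir screen directory; feature subfolders are created.
#' @export
write_screen_inputs <- function(well_features, dir) {
  feats <- c("1_PercentWPBarea" = "PercentWPBarea",
             "2_TotalWPBnrPerCellNR" = "TotalWPBnrPerCellNR",
             "3_TotalWPBrawIntDenPerCellNR" = "TotalWPBrawIntDenPerCellNR",
             "4_TotalFoVpercentWPBnr" = "TotalFoVpercentWPBnr")
  for (folder in names(feats)) {
    d <- file.path(dir, folder)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (p in unique(well_features$plate)) {
      sub <- well_features[well_features$plate == p, ]
      utils::write.table(
        data.frame(plate = sub$plate, well = sub$well, value = sub[[feats[[folder]]]]),
        file.path(d, paste0(p, ".txt")),
        sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @param path one 3-column file.
#' @rdname write_screen_inputs
#' @export
read_screen_input <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("plate", "well", "value"),
                         colClasses = c("character", "character", "numeric"))
  parse_well_id(x$well)
  as_tibble(x)
}
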