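#' Well identifiers
#'
#' Wells of a 96-well plate are written `"A01"`..`"H12"` (row letter A--H,
#' 2-digit column 01--12). `parse_well_id()` validates strictly and returns
#' 0-based row/column indices; `well_id()` is the inverse.
#'
#' @param text character vector of well identifiers.
#' @return `parse_well_id()`: a tibble with `well`, `row`, `col` (0-based).
#' @export
parse_well_id <- function(text) {
  bad <- !grepl("^[A-H](0[1-9]|1[0-2])$", text)
  if (any(bad)) {
    abort(sprintf("malformed well identifier: %s",
                  paste(unique(text[bad]), collapse = ", ")),
          class = "wpb_parse_error")
  }
  tibble(well = text,
         row = match(substr(text, 1, 1), LETTERS) - 1L,
         col = as.integer(substr(text, 2, 3)) - 1L)
}

#' @param row,col 0-based indices (row 0..7, col 0..11).
#' @rdname parse_well_id
#' @export
well_id <- function(row, col) {
  stopifnot(all(row >= 0 & row <= 7), all(col >= 0 & col <= 11))
  sprintf("%s%02d", LETTERS[row + 1], col + 1)
}

#' All wells of the 96-well plate, in row-major order
#' @return character vector `"A01"`..`"H12"`.
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Plate layout: well roles, fields per well, planted effects
#'
#' Describes one 96-well plate of a synthetic screen: each well has exactly
#' one role (`sample`, `negative_control`, `positive_control`) and optionally
#' a multiplicative effect on WPB count, length and/or intensity, emulating a
#' perturbation (e.g. vWF knockdown in positive-control wells).
#'
#' @param roles named character vector (well -> role) for non-sample wells;
#'   unlisted wells are samples.
#' @param fields_per_well fields of view acquired per well (default 5).
#' @param effects named list (well -> named numeric with any of `count`,
#'   `length`, `intensity`) of multiplicative effects.
#' @return list of class `plate_layout` with `wells` (tibble: well, role),
#'   `fields_per_well`, `effects`.
#' @export
plate_layout <- function(roles = NULL, fields_per_well = 5L, effects = list()) {
  wells <- plate_wells()
  role <- setNames(rep("sample", 96L), wells)
  if (!is.null(roles)) {
    parse_well_id(names(roles))  # validates
    ok <- roles %in% c("sample", "negative_control", "positive_control")
    if (!all(ok)) abort("plate_layout: unknown role(s).", class = "wpb_parameter_error")
    role[names(roles)] <- roles
  }
  if (length(effects)) parse_well_id(names(effects))
  structure(list(
    wells = tibble(well = wells, role = unname(role[wells])),
    fields_per_well = as.integer(fields_per_well),
    effects = effects), class = "plate_layout")
}

#' Default screening layout with scattered controls and optional planted hits
#'
#' Eight negative-control wells (non-targeting siRNA) on the main diagonal
#' A01..H08 and eight positive-control wells (vWF knockdown) at A09, B10,
#' C11, D12, E09, F10, G11, H12. The controls are deliberately scattered so
#' that no plate row or column is dominated by controls: the B-score median
#' polish fits row/column effects on all wells, and a column filled with one
#' control type would fold the control effect into the column effect.
#' Positive-control wells reduce WPB count to 10% and WPB intensity to 20% of
#' the sample level, emulating the vWF-knockdown phenotype. `planted_hits`
#' marks sample wells given `hit_effect` (default: more and brighter WPBs),
#' for recovery benchmarks.
#'
#' @param fields_per_well fields of view per well.
#' @param pos_effect,hit_effect named numeric effects (see [plate_layout()]).
#' @param planted_hits character vector of sample wells to perturb.
#' @return a [plate_layout()].
#' @export
screen_layout <- function(fields_per_well = 5L,
                          pos_effect = c(count = 0.1, intensity = 0.2),
                          planted_hits = character(),
                          hit_effect = c(count = 1.6, intensity = 1.3)) {
  neg <- well_id(0:7, 0:7)
  pos <- well_id(0:7, c(8, 9, 10, 11, 8, 9, 10, 11))
  if (any(planted_hits %in% c(neg, pos))) {
    abort("screen_layout: planted hits must be sample wells.", class = "wpb_parameter_error")
  }
  roles <- c(setNames(rep("negative_control", 8), neg),
             setNames(rep("positive_control", 8), pos))
  effects <- c(
    setNames(rep(list(pos_effect), 8), pos),
    setNames(rep(list(hit_effect), length(planted_hits)), planted_hits))
  plate_layout(roles = roles, fields_per_well = fields_per_well, effects = effects)
}

#' Generate a whole synthetic plate on disk
#'
#' Renders `96 * fields_per_well` field pairs (nuclear + WPB channel) with
#' the per-well effects of the layout applied to the base field spec, writes
#' them as 16-bit single-channel TIFFs named
#' `<well>_f<field>_ch<channel>.tif` under `dir`, writes the ground-truth
#' tables as CSV, and returns the truth. Per-field seeds are derived
#' deterministically from `seed`, the well index and the field index, so a
#' rerun is bit-identical.
#'
#' @param layout a [plate_layout()].
#' @param base_spec a [field_spec()] used for sample wells.
#' @param dir output directory (created if needed).
#' @param plate_id plate identifier used in file names and truth tables.
#' @param seed base seed (defaults to `base_spec$seed`).
#' @param wells optional subset of wells to render (default: the whole
#'   plate); useful for small fixtures.
#' @return invisible list with `dir`, `plate_id`, `layout`, and truth tibbles
#'   `wpbs`, `nuclei`, `wells` (per-well true mean count/length/intensity
#'   summaries).
#' @export
generate_plate <- function(layout, base_spec, dir, plate_id = "P1",
                           seed = base_spec$seed, wells = NULL) {
  stopifnot(inherits(layout, "plate_layout"), inherits(base_spec, "field_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_wells <- layout$wells$well
  if (is.null(wells)) wells <- all_wells
  stopifnot(all(wells %in% all_wells))
  truth_w <- list(); truth_n <- list()
  for (well in wells) {
    w <- match(well, all_wells)
    eff <- layout$effects[[well]]
    sp <- apply_effects(base_spec, eff)
    for (f in seq_len(layout$fields_per_well)) {
      sp$seed <- as.integer(seed + (w - 1L) * (layout$fields_per_well + 2L) + f)
      fld <- generate_field(sp)
      write_field_tiff(fld$nuclei_image, file.path(dir, sprintf("%s_f%d_ch1.tif", well, f)))
      write_field_tiff(fld$wpb_image, file.path(dir, sprintf("%s_f%d_ch2.tif", well, f)))
      if (nrow(fld$truth$wpbs)) {
        truth_w[[length(truth_w) + 1L]] <-
          dplyr::mutate(fld$truth$wpbs, plate = plate_id, well = well, field = f,
                        .before = 1)
      }
      truth_n[[length(truth_n) + 1L]] <-
        dplyr::mutate(fld$truth$nuclei, plate = plate_id, well = well, field = f,
                      .before = 1)
    }
  }
  wpbs <- if (length(truth_w)) dplyr::bind_rows(truth_w) else tibble()
  nuclei <- dplyr::bind_rows(truth_n)
  well_summary <- if (nrow(wpbs)) {
    dplyr::summarise(dplyr::group_by(wpbs, .data$well),
                     n_wpb = dplyr::n(),
                     mean_length_um = mean(.data$length_um),
                     frac_over_cut = mean(.data$length_um > 1.5),
                     total_intensity = sum(.data$total_intensity),
                     .groups = "drop")
  } else tibble()
  utils::write.csv(wpbs, file.path(dir, sprintf("%s_truth_wpbs.csv", plate_id)), row.names = FALSE)
  utils::write.csv(nuclei, file.path(dir, sprintf("%s_truth_nuclei.csv", plate_id)), row.names = FALSE)
  invisible(list(dir = dir, plate_id = plate_id, layout = layout,
                 wpbs = wpbs, nuclei = nuclei, wells = well_summary))
}

apply_effects <- function(spec, eff) {
  if (is.null(eff)) return(spec)
  if ("count" %in% names(eff)) {
    spec$wpb_per_cell <- spec$wpb_per_cell * eff[["count"]]
  }
  if ("length" %in% names(eff)) {
    spec$wpb_length_um$meanlog <- spec$wpb_length_um$meanlog + log(eff[["length"]])
  }
  if ("intensity" %in% names(eff)) {
    spec$wpb_intensity <- min(spec$wpb_intensity * eff[["intensity"]], 4095)
  }
  spec
}
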