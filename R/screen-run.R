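#' Score a screen: B-score normalization, Z scores, QC, hits
#'
#' Takes per-well values in long form and, per feature: normalizes every
#' plate of every replicate by the B-score method (two-way median polish on
#' all wells, residuals scaled by their MAD), computes robust Z scores per
#' replicate against the sample-well distribution of the whole replicate,
#' averages Z scores across replicates, computes Z' factors per replicate
#' from the normalized control values, per-well replicate SDs, and the hit
#' list at the Z threshold (strict inequality).
#'
#' @param well_values tibble with columns `feature`, `replicate`, `plate`,
#'   `well`, `role`, `value`.
#' @param z_threshold hit threshold on the replicate-averaged Z score.
#' @param annotations optional well-to-gene map (see [hit_list()]).
#' @return object of class `screen_scores`: `scores` (long: feature,
#'   replicate, plate, well, role, raw, b, z), `summary` (feature, plate,
#'   well, role, z_mean, sd_b), `hits`, `qc` (feature, replicate, z_prime),
#'   `z_threshold`.
#' @export
score_screen <- function(well_values, z_threshold = 2, annotations = NULL) {
  need <- c("feature", "replicate", "plate", "well", "role", "value")
  if (!all(need %in% names(well_values))) {
    abort(paste("score_screen: well_values needs columns:", paste(need, collapse = ", ")),
          class = "wpb_parameter_error")
  }
  if (sum(well_values$role == "negative_control") < 2 ||
      sum(well_values$role == "positive_control") < 2) {
    abort("score_screen: control wells missing or unannotated (need >= 2 of each).",
          class = "wpb_input_error")
  }
  wv <- dplyr::mutate(as_tibble(well_values), b = NA_real_, z = NA_real_)

  # B scores per (feature, replicate, plate)
  grp <- dplyr::group_split(dplyr::group_by(wv, .data$feature, .data$replicate, .data$plate))
  grp <- lapply(grp, function(g) {
    m <- well_matrix(g$well, g$value)
    b <- b_score_normalize(m)
    idx <- parse_well_id(g$well)
    g$b <- b[cbind(idx$row + 1L, idx$col + 1L)]
    g
  })
  wv <- dplyr::bind_rows(grp)

  # Z scores per (feature, replicate), screen-wide, sample wells as the null
  grp <- dplyr::group_split(dplyr::group_by(wv, .data$feature, .data$replicate))
  qc <- list()
  grp <- lapply(grp, function(g) {
    g$z <- z_scores(g$b, g$role)
    zp <- tryCatch(
      z_prime(g$b[g$role == "positive_control"], g$b[g$role == "negative_control"]),
      error = function(e) NA_real_)
    qc[[length(qc) + 1L]] <<- tibble(feature = g$feature[1], replicate = g$replicate[1],
                                     z_prime = zp)
    g
  })
  wv <- dplyr::bind_rows(grp)
  qc <- dplyr::bind_rows(qc)

  summary <- dplyr::summarise(
    dplyr::group_by(wv, .data$feature, .data$plate, .data$well, .data$role),
    z_mean = mean(.data$z), sd_b = sd(.data$b), raw_mean = mean(.data$value),
    .groups = "drop")

  hits <- dplyr::bind_rows(lapply(split(summary, summary$feature), function(s) {
    h <- hit_list(dplyr::rename(s, z = "z_mean"), threshold = z_threshold,
                  annotations = annotations)
    if (nrow(h)) dplyr::mutate(h, feature = s$feature[1], .before = 1) else tibble()
  }))

  structure(list(scores = dplyr::rename(wv, raw = "value"), summary = summary,
                 hits = hits, qc = qc, z_threshold = z_threshold),
            class = "screen_scores")
}

# 8 x 12 plate matrix (rows A..H) from well ids and values
well_matrix <- function(wells, values) {
  idx <- parse_well_id(wells)
  m <- matrix(NA_real_, 8, 12, dimnames = list(LETTERS[1:8], sprintf("%02d", 1:12)))
  m[cbind(idx$row + 1L, idx$col + 1L)] <- values
  m
}

#' Run screen-level scoring over replicated plate results
#'
#' Assembles the long per-well value table (all four features) from
#' [run_plate()] results, attaches well roles from the layout, and calls
#' [score_screen()]. Optionally writes the per-feature 3-column input
#' folders and the score/hit/QC tables under `out_dir`.
#'
#' @param replicates named list: replicate id -> list of `plate_result`s
#'   (or a single `plate_result`).
#' @param layout a [plate_layout()] carrying the well roles.
#' @param config a [pipeline_config()] (supplies the Z threshold).
#' @param annotations optional well-to-gene map.
#' @param out_dir optional output directory.
#' @return a `screen_scores` object (see [score_screen()]).
#' @export
run_screen <- function(replicates, layout, config = pipeline_config(),
                       annotations = NULL, out_dir = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  if (!any(layout$wells$role != "sample")) {
    abort("run_screen: layout has no annotated control wells.", class = "wpb_input_error")
  }
  feats <- c("PercentWPBarea", "TotalWPBnrPerCellNR",
             "TotalWPBrawIntDenPerCellNR", "TotalFoVpercentWPBnr")
  rows <- list()
  for (rep_id in names(replicates)) {
    prs <- replicates[[rep_id]]
    if (inherits(prs, "plate_result")) prs <- list(prs)
    for (pr in prs) {
      wf <- dplyr::left_join(pr$well_features, layout$wells, by = "well")
      for (fe in feats) {
        rows[[length(rows) + 1L]] <- tibble(
          feature = fe, replicate = rep_id, plate = wf$plate, well = wf$well,
          role = wf$role, value = wf[[fe]])
      }
      if (!is.null(out_dir)) {
        write_screen_inputs(pr$well_features, file.path(out_dir, rep_id))
      }
    }
  }
  scores <- score_screen(dplyr::bind_rows(rows),
                         z_threshold = config$z_threshold,
                         annotations = annotations)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores$scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(scores$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(scores$hits, file.path(out_dir, "hits.csv"), row.names = FALSE)
    utils::write.csv(scores$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  }
  scores
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("<screen_scores> %d feature(s), %d replicate(s), %d well-values\n",
              length(unique(x$scores$feature)), length(unique(x$scores$replicate)),
              nrow(x$scores)))
  cat(sprintf("  hits (Z > %g): %d\n", x$z_threshold, nrow(x$hits)))
  print(x$qc)
  invisible(x)
}

#' Tidy methods for screen scores
#'
#' `tidy()` returns the long per-well score table; `glance()` one row per
#' feature with hit counts and QC summaries.
#'
#' @param x a `screen_scores` object.
#' @param ... unused.
#' @method tidy screen_scores
#' @export
tidy.screen_scores <- function(x, ...) {
  dplyr::left_join(x$scores,
                   dplyr::select(x$summary, "feature", "plate", "well", "z_mean", "sd_b"),
                   by = c("feature", "plate", "well"))
}

#' @rdname tidy.screen_scores
#' @method glance screen_scores
#' @export
glance.screen_scores <- function(x, ...) {
  qc <- dplyr::summarise(dplyr::group_by(x$qc, .data$feature),
                         mean_z_prime = mean(.data$z_prime), .groups = "drop")
  sm <- dplyr::summarise(
    dplyr::group_by(x$summary, .data$feature),
    n_wells = dplyr::n(), median_sd_b = median(.data$sd_b, na.rm = TRUE),
    max_z = max(.data$z_mean, na.rm = TRUE), .groups = "drop")
  hits <- dplyr::count(x$hits, .data$feature, name = "n_hits")
  out <- dplyr::left_join(sm, qc, by = "feature")
  out <- dplyr::left_join(out, hits, by = "feature")
  out$n_hits[is.na(out$n_hits)] <- 0L
  out
}
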