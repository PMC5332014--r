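#' Plate heatmap of per-well values
#'
#' The standard 8 x 12 QC view: one tile per well, rows A--H top to bottom,
#' control wells outlined. Used for replicate-SD reproducibility maps and
#' score overviews.
#'
#' @param data tibble with `well`, a value column, and optionally `role`.
#' @param value name of the value column to map to fill.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_plate_heatmap <- function(data, value = "z_mean", title = NULL) {
  stopifnot(is.data.frame(data), "well" %in% names(data), value %in% names(data))
  idx <- parse_well_id(data$well)
  df <- dplyr::mutate(as_tibble(data),
                      row = factor(LETTERS[idx$row + 1], levels = rev(LETTERS[1:8])),
                      col = factor(idx$col + 1, levels = 1:12))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data[[value]])) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
  if ("role" %in% names(df)) {
    ctrl <- df[df$role != "sample", , drop = FALSE]
    if (nrow(ctrl)) {
      p <- p + ggplot2::geom_tile(data = ctrl, fill = NA, color = "red",
                                  linewidth = 0.8)
    }
  }
  p
}

#' Z-score overview of a scored screen
#'
#' Histogram of replicate-averaged Z scores per feature, with the hit
#' threshold marked; control wells drawn as a rug.
#'
#' @param object a `screen_scores` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot screen_scores
#' @export
autoplot.screen_scores <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s[s$role == "sample", ], ggplot2::aes(x = .data$z_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$z_threshold, linetype = 2, color = "red") +
    ggplot2::geom_rug(data = s[s$role != "sample", ],
                      ggplot2::aes(color = .data$role), sides = "b") +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_x") +
    ggplot2::labs(x = "Z score (replicate mean)", y = "sample wells") +
    ggplot2::theme_minimal()
}
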