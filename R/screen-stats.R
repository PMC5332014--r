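#' Per-well WPB statistics from per-field feature tables
#'
#' Computes the four per-well screening statistics, each as the mean of
#' per-field-of-view ratios:
#' \describe{
#'   \item{PercentWPBarea}{total area of WPBs with Feret diameter larger than
#'     the cut (1.5 um) over total WPB area;}
#'   \item{TotalWPBnrPerCellNR}{WPB count per cell;}
#'   \item{TotalWPBrawIntDenPerCellNR}{summed raw integrated density per
#'     cell;}
#'   \item{TotalFoVpercentWPBnr}{fraction of WPBs with Feret diameter larger
#'     than the cut.}
#' }
#' Fields with zero WPBs contribute an undefined 0/0 to the two ratio
#' features and are excluded from their means (but still count 0 toward the
#' per-cell features); fields with zero cells are excluded from the per-cell
#' features. A well where every field is degenerate yields NA values with a
#' warning.
#'
#' @param features per-object feature tibble for one well (needs columns
#'   `field`, `Area`, `Feret`, `RawIntDen`), e.g. from
#'   [extract_wpb_features()].
#' @param cell_counts tibble with `field` and `n_cells` covering every
#'   acquired field of the well.
#' @param feret_cut_um Feret length cut in um (strictly greater than).
#' @return a one-row tibble with the four features, `n_fov`, and the
#'   bookkeeping counts `n_fov_wpb` / `n_fov_cells` of fields contributing to
#'   the ratio / per-cell features.
#' @export
compute_well_features <- function(features, cell_counts, feret_cut_um = 1.5) {
  stopifnot(is.data.frame(cell_counts), all(c("field", "n_cells") %in% names(cell_counts)))
  f1 <- f2 <- f3 <- f4 <- numeric(0)
  n_fov_wpb <- 0L; n_fov_cells <- 0L
  for (f in sort(unique(cell_counts$field))) {
    ncell <- cell_counts$n_cells[match(f, cell_counts$field)]
    ft <- features[features$field == f, , drop = FALSE]
    nw <- nrow(ft)
    if (nw > 0) {
      n_fov_wpb <- n_fov_wpb + 1L
      big <- ft$Feret > feret_cut_um
      f1 <- c(f1, sum(ft$Area[big]) / sum(ft$Area))
      f4 <- c(f4, sum(big) / nw)
    }
    if (ncell > 0) {
      n_fov_cells <- n_fov_cells + 1L
      f2 <- c(f2, nw / ncell)
      f3 <- c(f3, sum(ft$RawIntDen) / ncell)
    }
  }
  if (n_fov_wpb == 0L && n_fov_cells == 0L) {
    warn("compute_well_features: all fields of view degenerate; well reported as missing")
  }
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  tibble(
    PercentWPBarea = mean_or_na(f1),
    TotalWPBnrPerCellNR = mean_or_na(f2),
    TotalWPBrawIntDenPerCellNR = mean_or_na(f3),
    TotalFoVpercentWPBnr = mean_or_na(f4),
    n_fov = length(unique(cell_counts$field)),
    n_fov_wpb = n_fov_wpb, n_fov_cells = n_fov_cells)
}

#' Two-way median polish
#'
#' Iteratively removes row and column medians from a matrix, accumulating an
#' overall effect, row effects and column effects, until the total absolute
#' residual change falls below `tol` or `max_iter` sweeps are done. Missing
#' values are allowed and ignored by the medians.
#'
#' @param x numeric matrix.
#' @param max_iter maximum number of sweeps.
#' @param tol convergence tolerance on the change of the total absolute
#'   residual.
#' @return list with `overall`, `row`, `col`, `residuals`, `iter`,
#'   `converged`.
#' @export
median_polish <- function(x, max_iter = 10L, tol = 1e-6) {
  stopifnot(is.matrix(x))
  if (all(is.na(x))) abort("median_polish: all values missing.", class = "wpb_parameter_error")
  z <- x
  t0 <- 0
  re <- rep(0, nrow(x)); ce <- rep(0, ncol(x))
  oldsum <- sum(abs(z), na.rm = TRUE)
  iter <- 0L; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    rd <- apply(z, 1, median, na.rm = TRUE)
    rd[is.na(rd)] <- 0
    z <- sweep(z, 1, rd)
    re <- re + rd
    d <- median(ce)
    ce <- ce - d; t0 <- t0 + d
    cd <- apply(z, 2, median, na.rm = TRUE)
    cd[is.na(cd)] <- 0
    z <- sweep(z, 2, cd)
    ce <- ce + cd
    d <- median(re)
    re <- re - d; t0 <- t0 + d
    newsum <- sum(abs(z), na.rm = TRUE)
    if (abs(newsum - oldsum) < tol) { converged <- TRUE; break }
    oldsum <- newsum
  }
  list(overall = t0, row = re, col = ce, residuals = z,
       iter = iter, converged = converged)
}

#' B-score plate normalization
#'
#' Removes additive row and column (positional) effects from a plate by
#' two-way median polish and scales the residuals robustly:
#' `B = residual / (1.4826 * median(|residuals|))`. A plate whose residuals
#' have zero MAD (e.g. an exactly additive plate) gets all B scores set to 0.
#'
#' @param plate numeric matrix of per-well values (rows A..H, columns 1..12
#'   for a 96-well plate); NAs allowed.
#' @param max_iter,tol passed to [median_polish()].
#' @return matrix of B scores with attributes `fit` (the median-polish fit)
#'   and `mad` (the robust residual scale).
#' @export
b_score_normalize <- function(plate, max_iter = 10L, tol = 1e-6) {
  fit <- median_polish(plate, max_iter = max_iter, tol = tol)
  s <- 1.4826 * median(abs(fit$residuals), na.rm = TRUE)
  # a residual MAD at rounding-noise level means the plate is additive:
  # guard against dividing floating-point dust by floating-point dust
  eps <- 1e-9 * max(1, max(abs(plate), na.rm = TRUE))
  b <- if (is.na(s) || s < eps) {
    z <- fit$residuals
    z[!is.na(z)] <- 0
    z
  } else fit$residuals / s
  attr(b, "fit") <- fit
  attr(b, "mad") <- s
  b
}

#' Robust Z scores against the sample-well distribution
#'
#' `z_i = (x_i - median(samples)) / (1.4826 * MAD(samples))`, with location
#' and scale taken from sample wells only so controls and hits do not distort
#' the null.
#'
#' @param values numeric vector of per-well values.
#' @param roles character vector, same length: `"sample"`,
#'   `"negative_control"` or `"positive_control"`.
#' @return numeric vector of Z scores (all wells scored).
#' @export
z_scores <- function(values, roles) {
  stopifnot(length(values) == length(roles))
  s <- values[roles == "sample" & !is.na(values)]
  if (length(unique(s)) < 2) {
    abort("z_scores: need >= 2 distinct sample values.", class = "wpb_parameter_error")
  }
  scale <- mad(s)  # 1.4826 * median absolute deviation
  if (scale == 0) {
    abort("z_scores: sample MAD is zero; scale degenerate.", class = "wpb_parameter_error")
  }
  (values - median(s)) / scale
}

#' Z' (Z-prime) assay-quality factor
#'
#' `Z' = 1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|` with sample
#' standard deviations. Z' approaches 1 for perfectly separated control
#' distributions; values above 0 indicate a usable assay window.
#'
#' @param pos,neg numeric vectors of positive- / negative-control values
#'   (>= 2 each, distinct means).
#' @return a single numeric Z' value.
#' @export
z_prime <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    abort("z_prime: need >= 2 values per control group.", class = "wpb_parameter_error")
  }
  sep <- abs(mean(pos) - mean(neg))
  if (sep == 0) {
    abort("z_prime: control means are equal; separation undefined.", class = "wpb_parameter_error")
  }
  1 - 3 * (sd(pos) + sd(neg)) / sep
}

#' Per-well standard deviation across replicates
#'
#' @param replicates list (length >= 2) of aligned numeric vectors or
#'   matrices of per-well values.
#' @return object of the same shape with the per-well sample SD.
#' @export
replicate_sd <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2) {
    abort("replicate_sd: need >= 2 replicates.", class = "wpb_parameter_error")
  }
  d <- dim(replicates[[1]])
  arr <- matrix(unlist(lapply(replicates, as.numeric)),
                ncol = length(replicates))
  out <- apply(arr, 1, sd)
  if (!is.null(d)) dim(out) <- d
  out
}

#' Hits above a Z-score threshold
#'
#' Sample wells with `z` strictly greater than the threshold, sorted by
#' decreasing score, optionally annotated with gene symbols.
#'
#' @param scores tibble with columns `well`, `z` and optionally `role` and
#'   `plate`; only wells with `role == "sample"` (or all wells when no role
#'   column) are eligible.
#' @param threshold Z-score threshold (strict inequality; default 2).
#' @param annotations optional well-to-gene map: a named character vector or
#'   a tibble with `well` and `gene`.
#' @return tibble of hits, ranked by decreasing `z`.
#' @export
hit_list <- function(scores, threshold = 2, annotations = NULL) {
  stopifnot(is.data.frame(scores), all(c("well", "z") %in% names(scores)))
  out <- scores
  if ("role" %in% names(out)) out <- out[out$role == "sample", , drop = FALSE]
  out <- out[!is.na(out$z) & out$z > threshold, , drop = FALSE]
  out <- out[order(-out$z), , drop = FALSE]
  if (!is.null(annotations)) {
    ann <- if (is.data.frame(annotations)) annotations
           else tibble(well = names(annotations), gene = unname(annotations))
    out <- dplyr::left_join(out, ann, by = "well")
  }
  as_tibble(out)
}
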