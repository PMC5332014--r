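toy_features <- function(field, areas, ferets, intden = rep(1, length(areas))) {
  tibble::tibble(field = field, Area = areas, Feret = ferets, RawIntDen = intden)
}

test_that("the four per-well statistics reproduce hand-computed toy values", {
  # f4: 2 of 4 rods exceed 1.5 um
  ft <- toy_features(1, rep(1, 4), c(1.0, 2.0, 2.0, 1.2))
  wf <- compute_well_features(ft, tibble::tibble(field = 1, n_cells = 4))
  expect_equal(wf$TotalFoVpercentWPBnr, 0.5)
  # f1: areas {1,1,2} with Ferets {1.0,2.0,2.0} -> 3/4
  ft <- toy_features(1, c(1, 1, 2), c(1.0, 2.0, 2.0))
  wf <- compute_well_features(ft, tibble::tibble(field = 1, n_cells = 3))
  expect_equal(wf$PercentWPBarea, 0.75)
  # f2: two fields, 10 WPBs / 5 cells and 20 WPBs / 5 cells -> mean(2, 4) = 3
  ft <- dplyr::bind_rows(toy_features(1, rep(1, 10), rep(1, 10)),
                         toy_features(2, rep(1, 20), rep(1, 20)))
  wf <- compute_well_features(ft, tibble::tibble(field = 1:2, n_cells = c(5, 5)))
  expect_equal(wf$TotalWPBnrPerCellNR, 3)
  # f3: summed RawIntDen per cell
  ft <- toy_features(1, c(1, 1), c(1, 1), intden = c(300, 700))
  wf <- compute_well_features(ft, tibble::tibble(field = 1, n_cells = 4))
  expect_equal(wf$TotalWPBrawIntDenPerCellNR, 250)
})

test_that("degenerate fields of view are excluded per feature", {
  # field 2 has no WPBs: excluded from the ratio features, counts 0 per cell
  ft <- toy_features(1, c(1, 1), c(2.0, 1.0))
  cc <- tibble::tibble(field = 1:2, n_cells = c(2, 4))
  wf <- compute_well_features(ft, cc)
  expect_equal(wf$PercentWPBarea, 0.5)       # only field 1
  expect_equal(wf$TotalFoVpercentWPBnr, 0.5)
  expect_equal(wf$TotalWPBnrPerCellNR, mean(c(1, 0)))
  expect_equal(wf$n_fov_wpb, 1L)
  expect_equal(wf$n_fov_cells, 2L)
  # all fields degenerate -> NA well, warned
  expect_warning(
    wf0 <- compute_well_features(toy_features(integer(), numeric(), numeric()),
                                 tibble::tibble(field = 1, n_cells = 0)),
    "degenerate")
  expect_true(is.na(wf0$PercentWPBarea) && is.na(wf0$TotalWPBnrPerCellNR))
})

test_that("B scores vanish on exactly additive plates and ignore constants", {
  r <- rnorm(8); c <- rnorm(12)
  plate <- outer(r, c, "+") + 5
  b <- b_score_normalize(plate)
  expect_true(all(abs(b) < 1e-12))
  # adding a constant changes nothing
  x <- matrix(withr::with_seed(4, rnorm(96)), 8, 12)
  expect_equal(b_score_normalize(x + 100), b_score_normalize(x),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(b_score_normalize(matrix(NA_real_, 8, 12)),
               class = "wpb_parameter_error")
})

test_that("a single outlier dominates the B scores; exact additivity degenerates to 0", {
  # additive plate + mild noise so the residual MAD is positive
  plate <- outer(1:4, c(2, 5, 1, 9), "+") +
    withr::with_seed(8, matrix(rnorm(16, 0, 0.2), 4, 4))
  plate[2, 3] <- plate[2, 3] + 50
  b <- b_score_normalize(plate)
  expect_equal(which.max(abs(b)), which(row(plate) == 2 & col(plate) == 3))
  expect_gt(abs(b[2, 3]), 10)
  # without noise the non-outlier residuals are all 0, the MAD guard fires
  # and every B score is 0 by definition
  exact <- outer(1:4, c(2, 5, 1, 9), "+")
  exact[2, 3] <- exact[2, 3] + 50
  expect_true(all(b_score_normalize(exact) == 0))
})

test_that("median polish, run to convergence, matches the long-run reference polish", {
  for (i in 1:10) {
    x <- matrix(withr::with_seed(i, rnorm(96, 10, 3)), 8, 12)
    ours <- median_polish(x, max_iter = 200, tol = 1e-12)
    long <- stats::medpolish(x, eps = 1e-12, maxiter = 200, trace.iter = FALSE)
    expect_lt(max(abs(ours$residuals - long$residuals)), 1e-6)
    expect_lt(abs(ours$overall + sum(0) - long$overall), 1e-4)
  }
})

test_that("Z scores: median zero, hand value, affine invariance, degenerate errors", {
  v <- c(1, 2, 3, 4, 5)
  roles <- rep("sample", 5)
  z <- z_scores(v, roles)
  expect_equal(z[3], 0)
  expect_equal(z[5], 2 / 1.4826, tolerance = 1e-12)
  expect_equal(z_scores(3 * v - 7, roles), z, tolerance = 1e-12)
  expect_error(z_scores(rep(1, 5), roles), class = "wpb_parameter_error")
  expect_error(z_scores(c(1, 1, 1, 1, 9), roles), class = "wpb_parameter_error")  # MAD 0
  # location/scale from samples only
  z2 <- z_scores(c(v, 100), c(roles, "positive_control"))
  expect_equal(z2[1:5], z)
})

test_that("Z-prime: closed forms, monotonicity, degenerate separation", {
  exact <- function(mu, sigma, n = 8) {
    x <- withr::with_seed(1, rnorm(n))
    mu + sigma * as.numeric(scale(x))
  }
  expect_equal(z_prime(exact(100, 5), exact(200, 5)), 0.7)
  expect_equal(z_prime(c(5, 5, 5), c(9, 9)), 1)
  expect_lt(z_prime(exact(100, 10), exact(200, 5)),
            z_prime(exact(100, 5), exact(200, 5)))
  expect_error(z_prime(c(1, 2), c(1.5, 1.5)), class = "wpb_parameter_error")
  expect_error(z_prime(1, c(1, 2)), class = "wpb_parameter_error")
})

test_that("replicate SD: zeros on identical replicates, sqrt2 on {1,3}, symmetric", {
  a <- matrix(1:12, 3, 4)
  expect_true(all(replicate_sd(list(a, a)) == 0))
  expect_equal(replicate_sd(list(1, 3)), sqrt(2))
  b <- a + 2
  expect_equal(replicate_sd(list(a, b)), replicate_sd(list(b, a)))
  expect_error(replicate_sd(list(a)), class = "wpb_parameter_error")
})

test_that("hit list uses a strict threshold and joins annotations", {
  sc <- tibble::tibble(well = c("A02", "B02", "C02"), z = c(2.5, 1.9, 2.0),
                       role = "sample")
  h <- hit_list(sc, threshold = 2)
  expect_equal(nrow(h), 1)
  expect_equal(h$well, "A02")
  expect_equal(nrow(hit_list(sc, threshold = 3)), 0)
  h2 <- hit_list(sc, annotations = c(A02 = "GRK2"))
  expect_equal(h2$gene, "GRK2")
  # controls never appear
  sc$role <- c("positive_control", "sample", "sample")
  expect_equal(nrow(hit_list(sc, threshold = 2)), 0)
})

test_that("score_screen wires B scores, Z scores, QC and hits together", {
  wells <- plate_wells()
  layout <- screen_layout(fields_per_well = 1)
  roles <- setNames(layout$wells$role, layout$wells$well)
  mk <- function(rep_seed) {
    vals <- withr::with_seed(rep_seed, rnorm(96, 100, 2))
    vals[roles == "positive_control"] <- vals[roles == "positive_control"] - 50
    vals[wells == "D05"] <- vals[wells == "D05"] + 30   # planted hit
    tibble::tibble(feature = "TotalWPBrawIntDenPerCellNR", replicate = paste0("R", rep_seed),
                   plate = "P1", well = wells, role = unname(roles), value = vals)
  }
  scores <- score_screen(dplyr::bind_rows(mk(1), mk(2)))
  expect_s3_class(scores, "screen_scores")
  expect_true("D05" %in% scores$hits$well)
  sm <- scores$summary
  expect_gt(mean(sm$z_mean[sm$role == "negative_control"]),
            mean(sm$z_mean[sm$role == "positive_control"]))
  expect_true(all(scores$qc$z_prime > 0))
  td <- tidy(scores)
  expect_true(all(c("feature", "replicate", "b", "z", "z_mean") %in% names(td)))
  gl <- glance(scores)
  expect_equal(nrow(gl), 1)
  expect_gte(gl$n_hits, 1)
  p <- autoplot(scores)
  expect_s3_class(p, "ggplot")
  expect_error(score_screen(dplyr::mutate(mk(1), role = "sample")),
               class = "wpb_input_error")
})
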