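test_that("bioclim envelope: median scores 1, outside envelope 0", {
  tmpl <- raster_template(0, 0, 10, 10, 0.5)
  cc <- cell_centers(tmpl)
  b1 <- set_values_rowmajor(tmpl, cc[, 1])
  b2 <- set_values_rowmajor(tmpl, cc[, 2])
  st <- raster_stack(list(e1 = b1, e2 = b2))
  # presences inside the box [3,7]x[3,7], uniform
  set.seed(31)
  pres <- occurrence_table(rep("sp", 60), runif(60, 3, 7), runif(60, 3, 7))
  suit <- bioclim_envelope(pres, st)
  pv <- extract_values_to_points(occ_xy(pres), st)
  # a cell at (about) the presence median in both bands scores near 1
  med <- cbind(median(pv$e1), median(pv$e2))
  expect_gte(locate_cells(suit, med)$value, 0.9)
  # outside the presence min-max -> exactly 0
  expect_equal(locate_cells(suit, cbind(0.25, 5.25))$value, 0)
  expect_equal(locate_cells(suit, cbind(9.75, 9.75))$value, 0)
  # inside the box strictly positive; outside zero (construction)
  vals <- as.vector(t(suit$values))
  inside <- cc[, 1] >= min(pv$e1) & cc[, 1] <= max(pv$e1) &
    cc[, 2] >= min(pv$e2) & cc[, 2] <= max(pv$e2)
  strictly_out <- cc[, 1] < min(pv$e1) | cc[, 1] > max(pv$e1) |
    cc[, 2] < min(pv$e2) | cc[, 2] > max(pv$e2)
  expect_true(all(vals[inside] > 0))
  expect_true(all(vals[strictly_out] == 0))
  # held-out presences score above uniform background on average
  set.seed(32)
  held <- occurrence_table(rep("sp", 40), runif(40, 3, 7), runif(40, 3, 7))
  bg <- occurrence_table(rep("bg", 200), runif(200, 0, 10), runif(200, 0, 10))
  expect_gt(mean(locate_cells(suit, occ_xy(held))$value),
            mean(locate_cells(suit, occ_xy(bg))$value))
  # constant band skipped with warning
  stc <- raster_stack(list(e1 = b1, flat = set_values_rowmajor(tmpl, rep(1, nrow(cc)))))
  expect_warning(bioclim_envelope(pres, stc), "constant predictor band")
})

test_that("random pseudo-absences respect area, distance and seed", {
  area <- study_area_rect(0, 0, 10, 10)
  pa <- pseudo_absences_random(NULL, area, n = 10, seed = 3)
  expect_equal(nrow(pa), 10L)
  expect_true(all(area_contains(area, occ_xy(pa))))
  pres <- occurrence_table(rep("sp", 5), runif(5, 4, 6), runif(5, 4, 6))
  pa2 <- pseudo_absences_random(pres, area, n = 30, min_dist = 2, seed = 4)
  d <- cross_dist(occ_xy(pa2), occ_xy(pres))
  expect_true(all(apply(d, 1, min) >= 2))
  expect_identical(pseudo_absences_random(pres, area, 30, 2, seed = 4), pa2)
  # infeasible request errors with achieved count
  expect_error(pseudo_absences_random(
    occurrence_table("p", 5, 5), study_area_rect(4.9, 4.9, 5.1, 5.1),
    n = 5, min_dist = 10, max_tries = 3), "could only place")
})

test_that("evidence-based pseudo-absences follow the sampling density", {
  area <- study_area_rect(0, 0, 10, 10)
  tmpl <- raster_template(0, 0, 10, 10, 0.5)
  # all group sampling concentrated in the left half
  set.seed(33)
  grp <- occurrence_table(rep("g", 300), runif(300, 0, 4.5), runif(300, 0, 10))
  pres <- occurrence_table(rep("f", 3), c(1, 2, 3), c(9, 9, 9))
  pa <- pseudo_absences_evidence(grp, pres, area, tmpl, n = 100,
                                 bandwidth = 1.5, seed = 5)
  expect_gte(mean(pa$x < 5), 0.9)
  expect_identical(pseudo_absences_evidence(grp, pres, area, tmpl, n = 100,
                                            bandwidth = 1.5, seed = 5), pa)
  # focal presences blanket the sampled area -> no eligible cells
  dense <- expand.grid(x = seq(0.25, 4.75, 0.25), y = seq(0.25, 9.75, 0.25))
  pres_all <- occurrence_table(rep("f", nrow(dense)), dense$x, dense$y)
  expect_error(pseudo_absences_evidence(grp, pres_all, area, tmpl, n = 5,
                                        bandwidth = 0.6, min_dist = 1),
               "no eligible cells")
})

test_that("binary validation reproduces the worked confusion example", {
  s <- confusion_stats(tp = 40, fp = 5, fn = 10, tn = 45)
  expect_equal(s$accuracy, 0.85)
  expect_equal(s$sensitivity, 0.8)
  expect_equal(s$specificity, 0.9)
  expect_equal(s$tss, 0.7, tolerance = 1e-12)
  expect_equal(s$kappa, 0.7, tolerance = 1e-12)
  expect_equal(s$precision, 8 / 9, tolerance = 1e-12)
  # perfect prediction
  p <- confusion_stats(10, 0, 0, 10)
  expect_true(all(unlist(p[c("accuracy", "precision", "sensitivity",
                             "specificity", "kappa", "tss")]) == 1))
  # constant-1 prediction: specificity 0, tss = sensitivity - 1
  c1 <- confusion_stats(50, 50, 0, 0)
  expect_equal(c1$specificity, 0)
  expect_equal(c1$tss, c1$sensitivity - 1)
  # undefined ratios are NA, not 0
  expect_true(is.na(confusion_stats(0, 0, 3, 7)$precision))
  # class-symmetry of kappa and tss under tp<->tn, fp<->fn
  a <- confusion_stats(13, 4, 9, 21); b <- confusion_stats(21, 9, 4, 13)
  expect_equal(a$kappa, b$kappa)
  expect_equal(a$tss, b$tss)
})

test_that("validate_binary matches counting through the raster", {
  pred <- raster_grid(matrix(c(1, 0, 1, 0), 2, 2), 0, 0, 1)
  obs <- data.frame(x = c(0.5, 1.5, 0.5, 1.5, 5),
                    y = c(1.5, 1.5, 0.5, 0.5, 5),
                    obs = c(1, 1, 0, 0, 1))
  v <- validate_binary(obs, pred)
  expect_equal(v$counts$n_dropped, 1L)
  expect_equal(with(v$counts, tp + fp + fn + tn), 4L)
})

test_that("AUC: separable, ties, worked pair example", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auc_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_error(auc_score(c(1, 1), c(0.5, 0.6)), "one class is empty")
  # oracle equivalence on random sets
  set.seed(34)
  for (k in 1:10) {
    n <- sample(10:60, 1)
    obs <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    expect_equal(auc_score(obs, sc), auc_bruteforce(obs, sc), tolerance = 1e-12)
  }
})

test_that("niche overlap statistics on normalized rasters", {
  a <- raster_grid(matrix(c(0.6, 0.4), 1, 2))
  b <- raster_grid(matrix(c(0.4, 0.6), 1, 2))
  o <- niche_overlap(a, b)
  expect_equal(unname(o["D"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(niche_overlap(a, a)), c(1, 1), tolerance = 1e-12)
  dis_a <- raster_grid(matrix(c(1, 0), 1, 2))
  dis_b <- raster_grid(matrix(c(0, 1), 1, 2))
  expect_equal(unname(niche_overlap(dis_a, dis_b)["D"]), 0)
  expect_error(niche_overlap(raster_grid(matrix(0, 1, 2)), a), "zero-sum")
})

test_that("minimum convex hull area and degeneracy", {
  occ <- occurrence_table(rep("s", 4), c(0, 1, 1, 0), c(0, 0, 1, 1))
  h <- minimum_convex_hull(occ)
  expect_equal(h$area, 1.0)
  # interior points leave the hull unchanged
  occ2 <- occurrence_table(rep("s", 6), c(0, 1, 1, 0, 0.5, 0.2),
                           c(0, 0, 1, 1, 0.5, 0.7))
  expect_equal(minimum_convex_hull(occ2)$area, 1.0)
  expect_error(minimum_convex_hull(
    occurrence_table(rep("s", 3), c(0, 1, 2), c(0, 1, 2))), "collinear")
  expect_error(minimum_convex_hull(
    occurrence_table(rep("s", 2), c(0, 1), c(0, 1))), ">= 3 distinct")
})

test_that("create_sample_points lays regular lattices with exact counts", {
  sq <- study_area_rect(0, 0, 1, 1)
  pts <- create_sample_points(sq, 100)
  expect_equal(nrow(pts), 100L)
  expect_true(all(area_contains(sq, occ_xy(pts))))
  # two disjoint patches get points roughly proportional to area
  two <- read_mask(two_squares_geojson())
  p2 <- create_sample_points(two, 80)
  expect_equal(nrow(p2), 80L)
  left <- sum(p2$x < 1.5); right <- sum(p2$x > 1.5)
  expect_gt(left, 25); expect_gt(right, 25)
  # binary raster source
  g <- raster_grid(matrix(0, 10, 10), 0, 0, 1)
  g$values[3:6, 3:6] <- 1
  p3 <- create_sample_points(g, 9)
  expect_equal(nrow(p3), 9L)
  v <- locate_cells(g, occ_xy(p3))$value
  expect_true(all(v == 1))
})

test_that("raster utilities: extract, sum, area, rescale", {
  a <- raster_grid(matrix(c(1, 0, 1, NA), 2, 2), 0, 0, 0.5)
  b <- raster_grid(matrix(c(1, 1, 0, 1), 2, 2), 0, 0, 0.5)
  st <- raster_stack(list(a = a, b = b))
  # extraction at a cell center returns the band values
  ex <- extract_values_to_points(cbind(0.25, 0.75), st)
  expect_equal(unlist(ex), c(a = 1, b = 1))
  # off-grid point gives NA row
  expect_true(all(is.na(extract_values_to_points(cbind(9, 9), st))))
  # sum of maps ignores nodata by default, honours require_all
  sm <- sum_of_maps(st)
  expect_equal(sm$values[2, 2], 1)
  expect_true(is.na(sum_of_maps(st, require_all = TRUE)$values[2, 2]))
  expect_equal(sum_of_maps(raster_stack(list(a = b, b = b, c = b)))$values,
               b$values * 3)
  # area = presence cells x cell area (0.5 x 0.5 cells)
  g10 <- raster_grid(matrix(0, 5, 5), 0, 0, 0.5)
  g10$values[1:2, 1:5] <- 1
  expect_equal(area_of_distribution(g10), 10 * 0.25)
  expect_error(area_of_distribution(raster_grid(matrix(0.3, 2, 2))),
               "not binary")
  # rescale01
  r <- rescale01(raster_grid(matrix(c(2, 4, 6, 10), 2, 2)))
  expect_equal(range(r$values), c(0, 1))
  expect_error(rescale01(raster_grid(matrix(1, 2, 2))), "constant")
})
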