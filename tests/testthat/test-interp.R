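test_that("nearest-neighbour interpolation and its tie rule", {
  tmpl <- raster_template(0, 0, 2, 1, 0.5)
  # one sample -> constant raster
  g1 <- nn_interpolate(sample_set(1, 0.5, 7), tmpl)
  expect_true(all(g1$values == 7))
  # cell coincident with a sample takes its value
  s2 <- sample_set(c(0.25, 1.75), c(0.75, 0.75), c(1, 2))
  g2 <- nn_interpolate(s2, tmpl)
  expect_equal(locate_cells(g2, cbind(0.25, 0.75))$value, 1)
  expect_equal(locate_cells(g2, cbind(1.75, 0.75))$value, 2)
  # midpoint cell: tie goes to the first sample
  s3 <- sample_set(c(0.25, 1.25), c(0.75, 0.75), c(10, 20))
  g3 <- nn_interpolate(s3, tmpl)
  expect_equal(locate_cells(g3, cbind(0.75, 0.75))$value, 10)
  # mask: outside cells nodata
  gm <- nn_interpolate(s2, tmpl, study_area_rect(0, 0, 1, 1))
  expect_true(is.na(locate_cells(gm, cbind(1.75, 0.75))$value))
})

test_that("thin-plate spline: exactness, affine reproduction, smoothing limit", {
  tmpl <- raster_template(0, 0, 3, 3, 0.25)
  set.seed(21)
  x <- runif(12, 0.2, 2.8); y <- runif(12, 0.2, 2.8)
  z <- sin(x) + cos(y)
  # evaluate at sample locations by placing samples at cell centers
  xs <- (floor(x / 0.25) + 0.5) * 0.25
  ys <- (floor(y / 0.25) + 0.5) * 0.25
  s <- sample_set(xs, ys, z)
  g <- tps_interpolate(s, tmpl, lambda = 0)
  expect_lt(max(abs(locate_cells(g, cbind(xs, ys))$value - z)), 1e-8)
  # plane z = 2x + 3y + 1 reproduced everywhere
  sp <- sample_set(xs, ys, 2 * xs + 3 * ys + 1)
  gp <- tps_interpolate(sp, tmpl, lambda = 0)
  cc <- cell_centers(gp)
  expect_lt(max(abs(as.vector(t(gp$values)) - (2 * cc[, 1] + 3 * cc[, 2] + 1))),
            1e-6)
  # large lambda approaches the least-squares plane
  g_inf <- tps_interpolate(s, tmpl, lambda = 1e3)
  lsq <- lm(z ~ xs + ys)
  pred <- cbind(1, cc[, 1], cc[, 2]) %*% coef(lsq)
  expect_lt(max(abs(as.vector(t(g_inf$values)) - pred)), 0.02)
  # collinear samples with lambda = 0 are singular
  s_col <- sample_set(1:4, 1:4, c(1, 2, 3, 4))
  expect_error(tps_interpolate(s_col, tmpl, lambda = 0), "lambda > 0")
})

test_that("empirical variogram matches hand cases and the pure-nugget oracle", {
  # constant field: gamma = 0 in every bin
  set.seed(22)
  s_const <- sample_set(runif(30), runif(30), rep(5, 30))
  ev0 <- empirical_variogram(s_const, n_bins = 5)
  expect_true(all(ev0$gamma[!is.na(ev0$gamma)] == 0))
  # two points with values 0 and 2: single pair gamma = 2
  ev2 <- empirical_variogram(sample_set(c(0, 1), c(0, 0), c(0, 2)),
                             n_bins = 1, max_dist = 2)
  expect_equal(ev2$gamma, 2)
  expect_equal(ev2$n_pairs, 1L)
  # white noise: gamma ~ sigma^2 at all lags
  set.seed(23)
  sigma <- 2
  sw <- sample_set(runif(400, 0, 10), runif(400, 0, 10), rnorm(400, 0, sigma))
  evw <- empirical_variogram(sw, n_bins = 6)
  expect_true(all(abs(evw$gamma - sigma^2) / sigma^2 < 0.25, na.rm = TRUE))
  expect_error(empirical_variogram(sample_set(c(1, 1), c(2, 2), c(0, 1))),
               "coincident")
})

test_that("variogram fitting and kriging exactness/degeneracy", {
  set.seed(24)
  xq <- runif(40, 0, 10); yq <- runif(40, 0, 10)
  s <- sample_set(xq, yq, sin(xq / 2) + rnorm(40, 0, 0.1))
  ev <- empirical_variogram(s, n_bins = 8)
  vm <- fit_variogram(ev)
  expect_true(vm$model %in% c("exponential", "spherical", "gaussian"))
  expect_gte(vm$nugget, 0)
  expect_gte(vm$sill, vm$nugget)
  # semivariance is monotone for these models
  h <- seq(0.01, 20, length.out = 50)
  expect_true(all(diff(variogram_semivariance(vm, h)) >= -1e-9))

  # zero nugget: exact at sample locations (samples at cell centers)
  tmpl <- raster_template(0, 0, 4, 4, 0.5)
  xs <- c(0.25, 1.75, 2.75, 0.75, 3.25)
  ys <- c(0.25, 2.25, 0.75, 3.25, 3.25)
  z <- c(1, 3, 2, 5, 4)
  sk <- sample_set(xs, ys, z)
  vm0 <- variogram_model("exponential", 0, 1, 2)
  ok <- ordinary_krige(sk, vm0, tmpl)
  expect_lt(max(abs(locate_cells(ok$prediction, cbind(xs, ys))$value - z)),
            1e-6)
  expect_true(all(ok$variance$values >= 0))
  # constant samples -> constant prediction
  okc <- ordinary_krige(sample_set(xs, ys, rep(3, 5)), vm0, tmpl)
  expect_true(all(abs(okc$prediction$values - 3) < 1e-8))
  # duplicated locations are merged with a warning
  sd2 <- sample_set(c(xs, xs[1]), c(ys, ys[1]), c(z, 9))
  expect_warning(ordinary_krige(sd2, vm0, tmpl), "merged")
})

test_that("kriging beats nearest neighbour on a smooth seeded field", {
  # 1-D transect from an exponential-variogram Gaussian process
  set.seed(25)
  n <- 60
  x <- sort(runif(n, 0, 20))
  Sigma <- exp(-as.matrix(dist(x)) / 3)
  z <- as.vector(t(chol(Sigma + 1e-10 * diag(n))) %*% rnorm(n))
  hold <- seq(3, n, by = 5)
  # evaluation grid: one row of cells along the transect
  cell <- 0.05
  tmpl <- raster_template(0, 0, 20, cell, cell)
  xs_tr <- x[-hold]; zs_tr <- z[-hold]
  # snap training points to cell centers so exactness is well defined
  xs_tr <- (floor(xs_tr / cell) + 0.5) * cell
  s_tr <- sample_set(xs_tr, rep(cell / 2, length(xs_tr)), zs_tr)
  # the generating process has an exponential variogram; fit that model
  vm <- fit_variogram(empirical_variogram(s_tr, n_bins = 10), "exponential")
  kr <- suppressWarnings(ordinary_krige(s_tr, vm, tmpl))
  nn <- nn_interpolate(s_tr, tmpl)
  at <- cbind((floor(x[hold] / cell) + 0.5) * cell, cell / 2)
  mse_kr <- mean((locate_cells(kr$prediction, at)$value - z[hold])^2)
  mse_nn <- mean((locate_cells(nn, at)$value - z[hold])^2)
  expect_lt(mse_kr, mse_nn)
})

test_that("GLM surfaces: recovery, intercept-only, poisson simulation", {
  set.seed(26)
  tmpl <- raster_template(0, 0, 10, 10, 0.5)
  cc <- cell_centers(tmpl)
  b1 <- set_values_rowmajor(tmpl, cc[, 1] / 10)
  b2 <- set_values_rowmajor(tmpl, sin(cc[, 2]))
  st <- raster_stack(list(e1 = b1, e2 = b2))
  pts <- cbind(runif(80, 0.5, 9.5), runif(80, 0.5, 9.5))
  X <- extract_values_to_points(pts, st)
  # noiseless linear recovery
  s <- sample_set(pts[, 1], pts[, 2], 1.5 - 2 * X$e1 + 0.5 * X$e2)
  m <- glm_fit(s, st, "gaussian")
  expect_equal(unname(m$coefficients), c(1.5, -2, 0.5), tolerance = 1e-6)
  expect_equal(m$deviance_explained, 100, tolerance = 1e-6)
  pr <- glm_predict_surface(m, st)
  expect_equal(locate_cells(pr, pts)$value,
               s$value, tolerance = 1e-6)
  # rank-deficient design names the collinear band
  st_dup <- raster_stack(list(e1 = b1, e1copy = b1))
  expect_error(glm_fit(s, st_dup, "gaussian"), "collinear")
  # poisson recovery, n = 500: bias (mean error over replicates) < 0.05
  set.seed(27)
  errs <- vapply(1:20, function(k) {
    pts2 <- cbind(runif(500, 0.5, 9.5), runif(500, 0.5, 9.5))
    x2 <- extract_values_to_points(pts2, st)$e1
    y2 <- rpois(500, exp(0.5 + 1.2 * x2))
    mp <- glm_fit(sample_set(pts2[, 1], pts2[, 2], y2), st, "poisson")
    mp$coefficients[["e1"]] - 1.2
  }, 0)
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("sampling effort conserves mass and flattens for uniform points", {
  tmpl <- raster_template(0, 0, 10, 10, 0.2)
  # N coincident interior points -> total mass N
  expect_warning(occ <- occurrence_table(rep("s", 7), rep(5, 7), rep(5, 7)),
                 "duplicate")
  eff <- sampling_effort(occ, tmpl, bandwidth = 1)
  expect_equal(sum(eff$values) * 0.2^2, 7, tolerance = 0.01 * 7)
  # uniform points at adequate bandwidth: interior surface roughly flat
  set.seed(28)
  occ_u <- suppressWarnings(
    occurrence_table(rep("s", 800), runif(800, 0, 10), runif(800, 0, 10)))
  eff_u <- sampling_effort(occ_u, tmpl, bandwidth = 2.5)
  cc <- cell_centers(eff_u)
  interior <- cc[, 1] > 2.5 & cc[, 1] < 7.5 & cc[, 2] > 2.5 & cc[, 2] < 7.5
  v <- as.vector(t(eff_u$values))[interior]
  expect_lt(sd(v) / mean(v), 0.2)
})
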