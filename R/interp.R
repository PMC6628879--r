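# Spatial interpolators over raster templates. All interpolators honour the
# study-area mask exactly: cells outside the mask are nodata, everything is
# deterministic given its inputs.

#' Create a sample set (dependent value at coordinates)
#' @param x,y coordinates
#' @param value dependent variable
#' @param crs coordinate tag
#' @export
sample_set <- function(x, y, value, crs = "planar") {
  assert_that(length(x) == length(y) && length(y) == length(value),
              "x, y, value must have equal length")
  assert_that(length(x) >= 1L, "need at least one sample")
  assert_that(all(is.finite(x)) && all(is.finite(y)) && all(is.finite(value)),
              "non-finite sample")
  structure(data.frame(x = x, y = y, value = value),
            crs = crs, class = c("sample_set", "data.frame"))
}

#' Read a sample set from CSV with columns dependent, x, y
#' @param path CSV path
#' @param crs coordinate tag
#' @export
read_samples <- function(path, crs = "planar") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nms <- tolower(names(df))
  for (col in c("dependent", "x", "y"))
    if (!col %in% nms) stop2(paste0("missing required column: ", col))
  sample_set(as.numeric(df[[which(nms == "x")[1]]]),
             as.numeric(df[[which(nms == "y")[1]]]),
             as.numeric(df[[which(nms == "dependent")[1]]]), crs = crs)
}

# valid-cell selector: logical over row-major cells
mask_cells <- function(target, mask = NULL) {
  if (is.null(mask)) rep(TRUE, n_rows(target) * n_cols(target))
  else area_contains(mask, cell_centers(target))
}

fill_grid <- function(target, valid, vals) {
  out <- rep(NA_real_, length(valid))
  out[valid] <- vals
  set_values_rowmajor(target, out)
}

#' Nearest-neighbour interpolation
#'
#' Each cell inside the mask takes the value of its nearest sample
#' (Euclidean); ties resolve to the sample with the smallest index.
#'
#' @param samples sample_set
#' @param target raster_grid template (values ignored)
#' @param mask optional study_area; cells outside become nodata
#' @return raster_grid
#' @export
nn_interpolate <- function(samples, target, mask = NULL) {
  valid <- mask_cells(target, mask)
  cc <- cell_centers(target)[valid, , drop = FALSE]
  d <- cross_dist(cc, cbind(samples$x, samples$y))
  idx <- apply(d, 1L, which.min)
  fill_grid(target, valid, samples$value[idx])
}

tps_basis <- function(r) ifelse(r > 0, r * r * log(r), 0)

#' Thin-plate spline interpolation
#'
#' Radial basis r^2 log r plus an affine part. With `lambda = 0` the surface
#' passes through the samples exactly and reproduces any affine function of
#' the coordinates; `lambda` > 0 smooths towards (and in the limit onto) the
#' least-squares plane.
#'
#' @param samples sample_set (>= 3 non-collinear points for lambda = 0)
#' @param target raster_grid template
#' @param mask optional study_area
#' @param lambda smoothing parameter >= 0
#' @return raster_grid
#' @export
tps_interpolate <- function(samples, target, mask = NULL, lambda = 0) {
  assert_that(lambda >= 0, "lambda must be >= 0")
  n <- nrow(samples)
  assert_that(n >= 3L, "thin-plate spline needs >= 3 samples")
  P <- cbind(1, samples$x, samples$y)
  if (lambda == 0 && qr(P)$rank < 3L)
    stop2("collinear samples make the exact spline singular; use lambda > 0")
  K <- tps_basis(cross_dist(cbind(samples$x, samples$y),
                            cbind(samples$x, samples$y)))
  A <- rbind(cbind(K + n * lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(samples$value, rep(0, 3))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e)
                    stop2("singular spline system (duplicate or collinear samples); use lambda > 0"))
  w <- sol[seq_len(n)]; a <- sol[n + 1:3]
  valid <- mask_cells(target, mask)
  cc <- cell_centers(target)[valid, , drop = FALSE]
  Kc <- tps_basis(cross_dist(cc, cbind(samples$x, samples$y)))
  vals <- as.numeric(Kc %*% w) + a[1] + a[2] * cc[, 1] + a[3] * cc[, 2]
  fill_grid(target, valid, vals)
}

#' Empirical semivariogram of a sample set
#'
#' gamma(h) = mean over point pairs in the lag bin of (z_i - z_j)^2 / 2.
#'
#' @param samples sample_set
#' @param n_bins number of lag bins
#' @param max_dist maximum pair distance (default half the max distance)
#' @return data.frame (lag, gamma, n_pairs); empty bins have NA gamma
#' @export
empirical_variogram <- function(samples, n_bins = 12, max_dist = NULL) {
  n <- nrow(samples)
  assert_that(n >= 2L, "need >= 2 samples")
  d <- cross_dist(cbind(samples$x, samples$y), cbind(samples$x, samples$y))
  iu <- upper.tri(d)
  h <- d[iu]
  if (all(h == 0)) stop2("all points coincident")
  g <- 0.5 * (outer(samples$value, samples$value, "-")[iu])^2
  max_dist <- max_dist %||% (max(h) / 2)
  keep <- h > 0 & h <= max_dist
  bin <- pmin(floor(h[keep] / max_dist * n_bins) + 1L, n_bins)
  gamma <- tapply(g[keep], factor(bin, levels = seq_len(n_bins)), mean)
  counts <- tapply(rep(1, sum(keep)), factor(bin, levels = seq_len(n_bins)), sum)
  data.frame(lag = (seq_len(n_bins) - 0.5) * max_dist / n_bins,
             gamma = as.numeric(gamma),
             n_pairs = ifelse(is.na(counts), 0L, as.integer(counts)))
}

#' Theoretical semivariance of a fitted variogram model
#'
#' Returns `nugget + partial sill * f(h/range)`; at h = 0 the nugget, per the
#' conventional variogram (the kriging solver itself uses gamma(0) = 0 on the
#' diagonal so that zero-nugget kriging is exact at the data points).
#'
#' @param vm variogram_model
#' @param h distances
#' @export
variogram_semivariance <- function(vm, h) {
  psill <- vm$sill - vm$nugget
  s <- switch(vm$model,
    exponential = 1 - exp(-3 * h / vm$range),
    spherical = ifelse(h >= vm$range, 1,
                       1.5 * h / vm$range - 0.5 * (h / vm$range)^3),
    gaussian = 1 - exp(-3 * (h / vm$range)^2),
    stop2(paste0("unknown variogram model: ", vm$model)))
  vm$nugget + psill * s
}

#' Construct a variogram model
#' @param model "exponential", "spherical" or "gaussian"
#' @param nugget,sill,range model parameters (nugget >= 0, sill >= nugget,
#'   range > 0); `sill` is the total sill
#' @export
variogram_model <- function(model, nugget, sill, range) {
  assert_that(nugget >= 0 && sill >= nugget && range > 0,
              "need nugget >= 0, sill >= nugget, range > 0")
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares (weights = pair counts) over nugget, sill and
#' range. With `model = "best"` all three standard models are fitted and the
#' one with the lowest weighted residual is returned.
#'
#' @param ev empirical variogram table from [empirical_variogram()]
#' @param model "exponential", "spherical", "gaussian" or "best"
#' @return variogram_model with a `wss` attribute (weighted residual)
#' @export
fit_variogram <- function(ev, model = c("best", "exponential", "spherical",
                                        "gaussian")) {
  model <- match.arg(model)
  ev <- ev[!is.na(ev$gamma) & ev$n_pairs > 0, ]
  assert_that(nrow(ev) >= 3L, "need >= 3 non-empty variogram bins")
  fit_one <- function(mod) {
    obj <- function(par) {
      vm <- tryCatch(variogram_model(mod, par[1], par[1] + par[2], par[3]),
                     error = function(e) NULL)
      if (is.null(vm)) return(1e12)
      sum(ev$n_pairs * (variogram_semivariance(vm, ev$lag) - ev$gamma)^2)
    }
    start <- c(min(ev$gamma) * 0.5, max(ev$gamma) - min(ev$gamma) * 0.5,
               max(ev$lag) / 2)
    start[start <= 0] <- 1e-6
    opt <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = c(0, 1e-12, 1e-9 + max(ev$lag) * 1e-6))
    vm <- variogram_model(mod, opt$par[1], opt$par[1] + opt$par[2], opt$par[3])
    attr(vm, "wss") <- opt$value
    vm
  }
  if (model != "best") return(fit_one(model))
  fits <- lapply(c("exponential", "spherical", "gaussian"), fit_one)
  fits[[which.min(vapply(fits, attr, 0, "wss"))]]
}

# semivariance used inside the kriging system: 0 at distance 0. A tiny
# numerical nugget stabilizes the system for the gaussian model (whose
# covariance matrix is near-singular) without measurably breaking the
# exactness contract at data points.
krige_gamma <- function(vm, h) {
  eps <- (if (vm$model == "gaussian") 1e-3 else 1e-10) * max(vm$sill, 1e-12)
  ifelse(h == 0, 0, variogram_semivariance(vm, h) + eps)
}

#' Ordinary kriging
#'
#' Solves the standard ordinary-kriging system (with Lagrange multiplier)
#' per cell. Global neighbourhood up to 2000 samples, otherwise the 64
#' nearest samples per cell. Duplicate sample locations are merged to their
#' mean with a warning. With zero nugget the prediction at a sample location
#' equals the sample value.
#'
#' @param samples sample_set (>= 3)
#' @param vm variogram_model
#' @param target raster_grid template
#' @param mask optional study_area
#' @return list(prediction = raster_grid, variance = raster_grid)
#' @export
ordinary_krige <- function(samples, vm, target, mask = NULL) {
  assert_that(nrow(samples) >= 3L, "kriging needs >= 3 samples")
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    warning("duplicate sample locations merged to their mean")
    agg <- stats::aggregate(value ~ x + y, data = as.data.frame(samples), FUN = mean)
    samples <- sample_set(agg$x, agg$y, agg$value)
  }
  n <- nrow(samples)
  pts <- cbind(samples$x, samples$y)
  valid <- mask_cells(target, mask)
  cc <- cell_centers(target)[valid, , drop = FALSE]
  pred <- numeric(nrow(cc)); pvar <- numeric(nrow(cc))
  if (n <= 2000) {
    G <- krige_gamma(vm, cross_dist(pts, pts))
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    Ainv <- tryCatch(solve(A), error = function(e)
      stop2("singular kriging matrix"))
    g0 <- krige_gamma(vm, cross_dist(pts, cc))   # n x cells
    rhs <- rbind(g0, 1)
    sol <- Ainv %*% rhs                           # (n+1) x cells
    lam <- sol[seq_len(n), , drop = FALSE]
    mu <- sol[n + 1L, ]
    pred <- as.numeric(crossprod(lam, samples$value))
    pvar <- pmax(colSums(lam * g0) + mu, 0)
  } else {
    k <- 64L
    for (i in seq_len(nrow(cc))) {
      d <- sqrt((pts[, 1] - cc[i, 1])^2 + (pts[, 2] - cc[i, 2])^2)
      nb <- order(d)[seq_len(k)]
      G <- krige_gamma(vm, cross_dist(pts[nb, ], pts[nb, ]))
      A <- rbind(cbind(G, 1), c(rep(1, k), 0))
      g0 <- c(krige_gamma(vm, d[nb]), 1)
      sol <- solve(A, g0)
      pred[i] <- sum(sol[seq_len(k)] * samples$value[nb])
      pvar[i] <- max(sum(sol[seq_len(k)] * g0[seq_len(k)]) + sol[k + 1L], 0)
    }
  }
  list(prediction = fill_grid(target, valid, pred),
       variance = fill_grid(target, valid, pvar))
}

#' Fit a GLM of a sampled variable on raster predictors
#'
#' Extracts predictor values at the sample coordinates and fits a canonical-
#' link GLM. Reports coefficients, deviance and percent deviance explained.
#'
#' @param samples sample_set
#' @param predictors raster_stack
#' @param family "gaussian", "poisson" or "binomial"
#' @return object of class `glm_surface_model`
#' @export
glm_fit <- function(samples, predictors,
                    family = c("gaussian", "poisson", "binomial")) {
  family <- match.arg(family)
  X <- extract_values_to_points(cbind(samples$x, samples$y), predictors)
  ok <- stats::complete.cases(X)
  assert_that(all(ok), "samples fall on nodata predictor cells")
  df <- data.frame(y = samples$value, X)
  p <- ncol(X)
  assert_that(nrow(df) > p + 1L, "need n > p + 1 samples")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < p + 1L) {
    drop_idx <- setdiff(seq_len(p + 1L), qrX$pivot[seq_len(qrX$rank)]) - 1L
    stop2(paste0("rank-deficient design; collinear band(s): ",
                 paste(colnames(X)[drop_idx], collapse = ", ")))
  }
  fit <- stats::glm(y ~ ., data = df, family = family)
  if (!fit$converged) stop2("GLM did not converge")
  structure(list(fit = fit, family = family, bands = colnames(X),
                 coefficients = stats::coef(fit),
                 deviance = stats::deviance(fit),
                 null_deviance = fit$null.deviance,
                 deviance_explained = 100 * (1 - stats::deviance(fit) /
                                               fit$null.deviance)),
            class = "glm_surface_model")
}

#' Predict a GLM surface over raster predictors
#' @param model glm_surface_model
#' @param predictors raster_stack with the model's band names
#' @param mask optional study_area
#' @return raster_grid of response-scale predictions
#' @export
glm_predict_surface <- function(model, predictors, mask = NULL) {
  missing <- setdiff(model$bands, band_names(predictors))
  assert_that(length(missing) == 0L,
              paste0("missing predictor band(s): ", paste(missing, collapse = ", ")))
  tmpl <- predictors$bands[[1L]]
  valid <- mask_cells(tmpl, mask)
  M <- stack_matrix(predictors)[valid, model$bands, drop = FALSE]
  ok <- stats::complete.cases(M)
  vals <- rep(NA_real_, nrow(M))
  vals[ok] <- stats::predict(model$fit,
                             newdata = as.data.frame(M[ok, , drop = FALSE]),
                             type = "response")
  fill_grid(tmpl, valid, vals)
}

#' Kernel density map of sampling effort
#'
#' Quartic (biweight) kernel density over all occurrence records, normalized
#' so that cell_area * sum(density) equals the number of records whose
#' kernels lie inside the mask (up to edge truncation).
#'
#' @param points occurrence_table (all records, any species)
#' @param target raster_grid template
#' @param mask optional study_area
#' @param bandwidth kernel radius > 0
#' @return raster_grid of densities (per unit area)
#' @export
sampling_effort <- function(points, target, mask = NULL, bandwidth) {
  assert_that(bandwidth > 0, "bandwidth must be > 0")
  valid <- mask_cells(target, mask)
  cc <- cell_centers(target)[valid, , drop = FALSE]
  d <- cross_dist(cc, occ_xy(points)) / bandwidth
  K <- (1 - d^2)^2 * (d <= 1)
  dens <- rowSums(K) * 3 / (pi * bandwidth^2)
  fill_grid(target, valid, dens)
}
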