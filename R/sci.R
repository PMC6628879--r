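# Composition interpolation: NMDS of a beta-diversity matrix, a spatial-
# autocorrelation premise check on the axis scores, interpolation of the
# scores to rasters, an RGB composite, and unsupervised classification into
# bioregions. The phylogenetic variant (PCI) is the identical pipeline fed
# the phylogenetic beta matrix; there is no separate code path.

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 with monotone regression (vegan::monoMDS), best of
#' `n_restarts` starts (metric-scaling start plus random configurations).
#' Scores are column-centered. Deterministic given `seed`.
#'
#' @param d dissimilarity_matrix (or any symmetric matrix / dist)
#' @param k number of axes
#' @param n_restarts random restarts (>= 1)
#' @param max_iter maximum iterations per start
#' @param seed integer seed
#' @return list of class `ordination_result`: `scores` (site x k), `stress`,
#'   `k`, `n_restarts`, `seed`
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, max_iter = 500,
                            seed = 1) {
  m <- as.matrix(d)
  n <- nrow(m)
  assert_that(n >= k + 1, "need at least k + 1 sites")
  off <- m[upper.tri(m)]
  if (max(off) - min(off) < 1e-15)
    stop2("degenerate ordination: all dissimilarities equal")
  dd <- stats::as.dist(m)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(child_seed(seed, r))
    init <- if (r == 1L) {
      y <- suppressWarnings(stats::cmdscale(dd, k = k))
      if (ncol(y) < k) cbind(y, matrix(stats::rnorm(n * (k - ncol(y)), 0, 1e-4),
                                       n, k - ncol(y))) else y
    } else matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                          maxit = max_iter)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  scores <- scale(best$points, center = TRUE, scale = FALSE)
  colnames(scores) <- paste0("axis", seq_len(k))
  rownames(scores) <- rownames(m)
  structure(list(scores = scores, stress = best$stress, k = k,
                 n_restarts = n_restarts, seed = seed),
            class = "ordination_result")
}

#' Moran's I with inverse-distance weights
#'
#' Weights are 1/distance between locations, zero self-weight,
#' row-standardized. I = (n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2.
#'
#' @param z numeric values
#' @param coords two-column coordinate matrix
#' @param W optional precomputed weight matrix (overrides coords)
#' @return scalar I
#' @keywords internal
moran_i <- function(z, coords = NULL, W = NULL) {
  n <- length(z)
  if (is.null(W)) {
    d <- cross_dist(coords, coords)
    diag(d) <- Inf
    W <- 1 / d
    W <- W / rowSums(W)
  }
  zc <- z - mean(z)
  s2 <- sum(zc^2)
  if (s2 == 0) return(NA_real_)
  (n / sum(W)) * sum(W * outer(zc, zc)) / s2
}

#' Spatial-autocorrelation premise test for ordination axes
#'
#' Computes Moran's I for each axis with inverse-distance, row-standardized
#' weights between site centers and a two-sided permutation p-value. Spatial
#' structure in the scores is a premise of composition interpolation: a
#' warning is emitted when any axis has p > 0.05.
#'
#' @param ord ordination_result (or a score matrix)
#' @param coords site-center coordinates (site x 2)
#' @param n_perm permutations
#' @param seed integer seed
#' @return data.frame (axis, I, expected, p)
#' @export
moran_premise_test <- function(ord, coords, n_perm = 999, seed = 1) {
  scores <- if (inherits(ord, "ordination_result")) ord$scores else as.matrix(ord)
  n <- nrow(scores)
  assert_that(n >= 4L, "need >= 4 sites")
  d <- cross_dist(coords, coords)
  diag(d) <- Inf
  W <- 1 / d
  W <- W / rowSums(W)
  set.seed(seed)
  res <- lapply(seq_len(ncol(scores)), function(j) {
    z <- scores[, j]
    if (stats::sd(z) == 0)
      stop2(sprintf("axis %d has zero variance; Moran's I undefined", j))
    obs <- moran_i(z, W = W)
    perm <- vapply(seq_len(n_perm), function(k) moran_i(sample(z), W = W), 0)
    p_hi <- (1 + sum(perm >= obs)) / (n_perm + 1)
    p_lo <- (1 + sum(perm <= obs)) / (n_perm + 1)
    data.frame(axis = j, I = obs, expected = -1 / (n - 1),
               p = min(1, 2 * min(p_hi, p_lo)))
  })
  out <- do.call(rbind, res)
  if (any(out$p > 0.05))
    warning(sprintf("spatial-autocorrelation premise violated on axis(es): %s",
                    paste(out$axis[out$p > 0.05], collapse = ", ")))
  out
}

#' Interpolate ordination axes to rasters
#'
#' @param ord ordination_result
#' @param site_xy site-center coordinates matching the ordination rows
#' @param target raster_grid template
#' @param mask optional study_area
#' @param method "nn", "spline" or "kriging"
#' @param lambda spline smoothing (spline method)
#' @return raster_stack, one band per axis
#' @export
interpolate_axes <- function(ord, site_xy, target, mask = NULL,
                             method = c("nn", "spline", "kriging"),
                             lambda = 0) {
  method <- match.arg(method)
  bands <- lapply(seq_len(ord$k), function(j) {
    s <- sample_set(site_xy[, 1], site_xy[, 2], ord$scores[, j])
    switch(method,
           nn = nn_interpolate(s, target, mask),
           spline = tps_interpolate(s, target, mask, lambda = lambda),
           kriging = {
             ev <- empirical_variogram(s)
             vm <- fit_variogram(ev)
             ordinary_krige(s, vm, target, mask)$prediction
           })
  })
  names(bands) <- colnames(ord$scores)
  raster_stack(bands)
}

#' RGB composite of the first three stack bands
#'
#' Each band is min-max rescaled to integers 0..255 over its valid cells
#' (floor convention; the band maximum maps to 255).
#'
#' @param stack raster_stack with >= 3 bands
#' @return raster_stack of bands R, G, B
#' @export
rgb_composite <- function(stack) {
  assert_that(n_bands(stack) >= 3L, "RGB composite needs >= 3 bands")
  out <- lapply(1:3, function(j) {
    g <- stack$bands[[j]]
    v <- values_rowmajor(g)
    rng <- range(v, na.rm = TRUE)
    if (rng[1] == rng[2])
      stop2(paste0("constant band cannot be rescaled: ", band_names(stack)[j]))
    scaled <- floor((v - rng[1]) / (rng[2] - rng[1]) * 255)
    set_values_rowmajor(g, scaled)
  })
  names(out) <- c("R", "G", "B")
  raster_stack(out)
}

#' Unsupervised classification of a raster stack into regions
#'
#' Bands are z-scored over the jointly valid cells, then clustered with
#' k-means (best of `n_init` starts) or CLARA-style k-medoids (PAM on a
#' subsample of cells, all cells assigned to the nearest medoid).
#'
#' @param stack raster_stack
#' @param k number of classes (>= 2)
#' @param method "kmeans" or "kmedoids"
#' @param n_init restarts for k-means / subsample draws for k-medoids
#' @param seed integer seed
#' @param subsample_size k-medoids subsample (cells)
#' @return list of class `bioregion_map`: `labels` (raster_grid of 1..k),
#'   `method`, `k`, `seed`
#' @export
classify_regions <- function(stack, k, method = c("kmeans", "kmedoids"),
                             n_init = 10, seed = 1, subsample_size = 500) {
  method <- match.arg(method)
  assert_that(k >= 2, "k must be >= 2")
  M <- stack_matrix(stack)
  ok <- stats::complete.cases(M)
  X <- M[ok, , drop = FALSE]
  assert_that(nrow(X) >= k, "fewer valid cells than classes")
  if (nrow(unique(X)) < k) stop2("k exceeds the number of distinct cell vectors")
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  set.seed(seed)
  if (method == "kmeans") {
    fit <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100)
    lab <- fit$cluster
  } else {
    idx <- if (nrow(X) > subsample_size)
      sample(nrow(X), subsample_size) else seq_len(nrow(X))
    pam_fit <- cluster::pam(X[idx, , drop = FALSE], k = k, pamonce = 5)
    med <- X[idx[pam_fit$id.med], , drop = FALSE]
    lab <- apply(cross_dist(X, med), 1L, which.min)
  }
  out <- rep(NA_real_, nrow(M))
  out[ok] <- lab
  structure(list(labels = set_values_rowmajor(stack$bands[[1L]], out),
                 method = method, k = k, seed = seed),
            class = "bioregion_map")
}

#' End-to-end composition-interpolation pipeline
#'
#' Occurrences -> hex community -> beta matrix (taxonomic for SCI,
#' phylogenetic for PCI) -> NMDS -> premise test -> axis rasters
#' (+ RGB composite when k >= 3) -> optional bioregion classification.
#'
#' @param occ occurrence_table
#' @param area study_area
#' @param side hexagon side
#' @param k_axes NMDS dimensions
#' @param target raster_grid template for interpolation
#' @param tree phylogeny; when supplied the phylogenetic beta matrix is used
#' @param method interpolation method
#' @param classify_k optional number of bioregion classes
#' @param classify_method "kmeans" or "kmedoids"
#' @param n_restarts,n_perm,seed see the component functions
#' @param strict_premise abort (instead of warn) when the premise fails
#' @return list: community, beta, ordination, moran, axes (stack),
#'   composite (or NULL), regions (bioregion_map or NULL)
#' @export
run_sci <- function(occ, area, side, k_axes = 2, target, tree = NULL,
                    method = "nn", classify_k = NULL,
                    classify_method = "kmeans", n_restarts = 10,
                    n_perm = 199, seed = 1, strict_premise = FALSE) {
  grid <- build_hex_grid(area, side)
  cm <- assign_points(occ, grid)
  fam <- if (is.null(tree)) "taxonomic" else "phylogenetic"
  beta <- beta_matrix(cm, family = fam, tree = tree)
  occupied <- rownames(beta[[1]])
  ord <- nmds_ordination(beta[[1]], k = k_axes, n_restarts = n_restarts,
                         seed = seed)
  site_xy <- cm$site_xy[match(as.integer(occupied), cm$sites), , drop = FALSE]
  moran <- withCallingHandlers(
    moran_premise_test(ord, site_xy, n_perm = n_perm, seed = seed),
    warning = function(w) {
      if (strict_premise && grepl("premise violated", conditionMessage(w)))
        stop2(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(moran$p > 0.05))
    warning(sprintf("spatial-autocorrelation premise violated on axis(es): %s",
                    paste(moran$axis[moran$p > 0.05], collapse = ", ")))
  axes <- interpolate_axes(ord, site_xy, target, area, method = method)
  composite <- if (k_axes >= 3) rgb_composite(axes) else NULL
  regions <- if (!is.null(classify_k))
    classify_regions(axes, k = classify_k, method = classify_method,
                     seed = seed) else NULL
  list(community = cm, beta = beta, ordination = ord, moran = moran,
       axes = axes, composite = composite, regions = regions)
}
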