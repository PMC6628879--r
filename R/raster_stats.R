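# Raster-stack statistics and ordination: correlation matrix, threshold-graph
# variable clustering, correlation PCA with scenario projection and the
# equal-share axis-significance rule, global Moran's I, and the raster
# variogram.

#' Pearson correlation matrix between stack bands
#'
#' Computed over the cells jointly valid in every band. Constant bands get a
#' missing row/column with a warning.
#'
#' @param stack raster_stack (>= 2 bands)
#' @return band x band correlation matrix
#' @export
raster_correlation <- function(stack) {
  assert_that(n_bands(stack) >= 2L, "need >= 2 bands")
  M <- stack_matrix(stack)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  assert_that(nrow(M) >= 3L, "need >= 3 jointly valid cells")
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0))
    warning(paste0("constant band(s): ",
                   paste(colnames(M)[sds == 0], collapse = ", ")))
  r <- suppressWarnings(stats::cor(M))
  diag(r) <- 1
  r
}

#' Cluster variables by correlation threshold
#'
#' Single-linkage grouping: bands are in one group when connected through
#' pairs with |r| >= t (connected components of the thresholded graph).
#'
#' @param corr correlation matrix
#' @param t threshold in (0, 1)
#' @return list of class `variable_clusters`: `groups` (list of band-name
#'   vectors), `threshold`
#' @export
cluster_variables <- function(corr, t) {
  assert_that(t > 0 && t < 1, "threshold must be in (0, 1)")
  nms <- rownames(corr)
  n <- nrow(corr)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!is.na(corr[i, j]) && abs(corr[i, j]) >= t) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(nms, roots)
  names(groups) <- NULL
  structure(list(groups = groups, threshold = t), class = "variable_clusters")
}

#' Correlation PCA of a raster stack
#'
#' Bands are standardized (z-score over jointly valid cells) before the
#' eigen-decomposition, appropriate for mixed-unit environmental variables;
#' covariance PCA is available behind `standardize = FALSE`. Component signs
#' are fixed so each component's largest-magnitude loading is positive.
#'
#' @param stack raster_stack
#' @param standardize correlation (TRUE, default) or covariance PCA
#' @return list of class `pca_model`: `center`, `scale`, `loadings`,
#'   `eigenvalues`, `percent_variance`
#' @export
pca_fit <- function(stack, standardize = TRUE) {
  M <- stack_matrix(stack)
  ok <- stats::complete.cases(M)
  X <- M[ok, , drop = FALSE]
  assert_that(nrow(X) > ncol(X), "need more valid cells than bands")
  ctr <- colMeans(X)
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  assert_that(all(scl > 0), "constant band; drop it before PCA")
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  S <- stats::cov(Z)
  eig <- eigen(S, symmetric = TRUE)
  L <- eig$vectors
  for (j in seq_len(ncol(L))) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) L[, j] <- -L[, j]
  }
  ev <- pmax(eig$values, 0)
  dimnames(L) <- list(colnames(M), paste0("PC", seq_len(ncol(L))))
  structure(list(center = ctr, scale = scl, loadings = L, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 bands = colnames(M), standardize = standardize),
            class = "pca_model")
}

pca_scores_matrix <- function(model, M) {
  Z <- sweep(sweep(M, 2L, model$center), 2L, model$scale, "/")
  Z %*% model$loadings
}

#' Component-score rasters for the training stack
#' @param model pca_model
#' @param stack raster_stack with the model's bands
#' @param n_axes number of leading components to return (default all)
#' @return raster_stack of score bands PC1..PCk
#' @export
pca_transform <- function(model, stack, n_axes = NULL) {
  assert_that(setequal(model$bands, band_names(stack)),
              "band names do not match the fitted model")
  M <- stack_matrix(stack)[, model$bands, drop = FALSE]
  ok <- stats::complete.cases(M)
  S <- matrix(NA_real_, nrow(M), ncol(model$loadings))
  S[ok, ] <- pca_scores_matrix(model, M[ok, , drop = FALSE])
  n_axes <- n_axes %||% ncol(S)
  out <- lapply(seq_len(n_axes), function(j)
    set_values_rowmajor(stack$bands[[1L]], S[, j]))
  names(out) <- colnames(model$loadings)[seq_len(n_axes)]
  raster_stack(out)
}

#' Project a fitted PCA onto a new scenario stack
#'
#' Applies the training means, scales and loadings unchanged to a stack of
#' the same band names (e.g. a future climate scenario).
#'
#' @inheritParams pca_transform
#' @param other_stack scenario raster_stack (same band names)
#' @export
pca_project <- function(model, other_stack, n_axes = NULL) {
  missing <- setdiff(model$bands, band_names(other_stack))
  extra <- setdiff(band_names(other_stack), model$bands)
  if (length(missing) || length(extra))
    stop2(sprintf("band-name mismatch; missing: [%s], extra: [%s]",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", ")))
  pca_transform(model, other_stack, n_axes = n_axes)
}

#' Equal-share axis-significance rule
#'
#' A component is retained when its percent variance strictly exceeds the
#' equal share 100/p for p input bands (e.g. 5.26% for 19 bands).
#'
#' @param model pca_model
#' @param p number of input bands (default: the fitted number)
#' @return list: `threshold` (rounded to 2 decimals), `significant`
#'   (component indices), `percent_variance`
#' @export
pca_axis_significance <- function(model, p = NULL) {
  p <- p %||% length(model$bands)
  threshold <- 100 / p
  sig <- which(model$percent_variance > threshold)
  list(threshold = round(threshold, 2), significant = sig,
       percent_variance = model$percent_variance)
}

# rook/queen binary contiguity between valid cells of a grid
contiguity_weights <- function(grid, neighborhood = c("queen", "rook")) {
  neighborhood <- match.arg(neighborhood)
  idx <- which(!is.na(grid$values), arr.ind = TRUE)
  n <- nrow(idx)
  key <- matrix(0L, n_rows(grid), n_cols(grid))
  key[idx] <- seq_len(n)
  offs <- if (neighborhood == "rook")
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs[k, 1]; cc <- idx[, 2] + offs[k, 2]
    ok <- rr >= 1 & rr <= n_rows(grid) & cc >= 1 & cc <= n_cols(grid)
    nb <- rep(0L, n)
    nb[ok] <- key[cbind(rr[ok], cc[ok])]
    has <- nb > 0L
    W[cbind(which(has), nb[has])] <- 1
  }
  list(W = W, values = grid$values[idx])
}

#' Global Moran's I of a raster
#'
#' Binary rook/queen contiguity weights over valid cells; permutation
#' p-value by shuffling the cell values.
#'
#' @param grid raster_grid
#' @param neighborhood "queen" (default) or "rook"
#' @param n_perm permutations
#' @param seed integer seed
#' @return list: I, expected, z, p, n_perm, seed
#' @export
global_moran_raster <- function(grid, neighborhood = c("queen", "rook"),
                                n_perm = 999, seed = 1) {
  cw <- contiguity_weights(grid, neighborhood)
  z <- cw$values
  n <- length(z)
  assert_that(n >= 4L, "need >= 4 valid cells")
  if (stats::sd(z) == 0) stop2("zero variance: Moran's I undefined")
  obs <- moran_i(z, W = cw$W)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(k) moran_i(sample(z), W = cw$W), 0)
  p_hi <- (1 + sum(perm >= obs)) / (n_perm + 1)
  p_lo <- (1 + sum(perm <= obs)) / (n_perm + 1)
  list(I = obs, expected = -1 / (n - 1),
       z = (obs - mean(perm)) / stats::sd(perm),
       p = min(1, 2 * min(p_hi, p_lo)),
       n_perm = n_perm, seed = seed, perm_mean = mean(perm))
}

#' Semivariogram of a raster
#'
#' Same semivariance contract as [empirical_variogram()] applied to valid
#' cell centers; for large grids cell pairs are subsampled to `max_pairs`
#' (seeded).
#'
#' @param grid raster_grid
#' @param n_bins lag bins
#' @param max_dist maximum lag
#' @param max_pairs subsampling cap on the number of cells considered
#' @param seed integer seed for the subsample
#' @return data.frame (lag, gamma, n_pairs)
#' @export
raster_variogram <- function(grid, n_bins = 12, max_dist = NULL,
                             max_pairs = 1e6, seed = 1) {
  v <- values_rowmajor(grid)
  ok <- which(!is.na(v))
  n_keep <- floor(sqrt(2 * max_pairs))
  if (length(ok) > n_keep) {
    set.seed(seed)
    ok <- sort(sample(ok, n_keep))
  }
  cc <- cell_centers(grid)[ok, , drop = FALSE]
  empirical_variogram(sample_set(cc[, 1], cc[, 2], v[ok]),
                      n_bins = n_bins, max_dist = max_dist)
}
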