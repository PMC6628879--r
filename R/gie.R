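# Kernel-based delimitation of areas of endemism (AoE). Each restricted-range
# species contributes a quartic kernel centered on its range centroid; the
# kernel bandwidth R is the analysis "scale" and the species weight
# w_s = 1 - r_s / R favours the most range-restricted species. Areas where
# two or more kernels pile up are candidate AoEs; a consensus across scales
# averages the per-scale surfaces after rescaling each to [0, 1].

#' Per-species range summaries for kernel endemism analysis
#'
#' @param occ occurrence_table
#' @return data.frame (sp, cx, cy, r, n_records): arithmetic centroid and
#'   maximum centroid-to-record distance per species
#' @export
species_range_summary <- function(occ) {
  sp <- unique(occ$sp)
  out <- lapply(sp, function(s) {
    xy <- occ_xy(occ)[occ$sp == s, , drop = FALSE]
    cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
    r <- max(sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2))
    data.frame(sp = s, cx = cx, cy = cy, r = r, n_records = nrow(xy))
  })
  do.call(rbind, out)
}

#' Kernel endemism surface at one scale
#'
#' Species with range radius r_s <= R contribute a quartic (biweight) kernel
#' K(u) = (1 - u^2)^2, u = distance/R, centered on their centroid and
#' weighted by w_s = 1 - r_s / R; wider-ranging species are excluded at this
#' scale and listed.
#'
#' @param summary output of [species_range_summary()]
#' @param R kernel radius (scale) > 0
#' @param target raster_grid template
#' @param mask optional study_area
#' @return list of class `aoe_surface`: `support` (raster_grid), `R`,
#'   `species` (contributing, with weights), `excluded`
#' @export
gie_scale <- function(summary, R, target, mask = NULL) {
  assert_that(R > 0, "R must be > 0")
  qual <- summary$r <= R
  excluded <- summary$sp[!qual]
  valid <- mask_cells(target, mask)
  cc <- cell_centers(target)[valid, , drop = FALSE]
  supp <- numeric(nrow(cc))
  if (!any(qual)) {
    warning(sprintf("no species qualifies at scale R = %g", R))
  } else {
    ctr <- cbind(summary$cx[qual], summary$cy[qual])
    w <- 1 - summary$r[qual] / R
    u <- cross_dist(cc, ctr) / R
    K <- (1 - u^2)^2 * (u <= 1)
    supp <- as.numeric(K %*% w)
  }
  structure(list(support = fill_grid(target, valid, supp), R = R,
                 species = data.frame(sp = summary$sp[qual],
                                      weight = if (any(qual)) 1 - summary$r[qual] / R else numeric(0)),
                 excluded = excluded),
            class = "aoe_surface")
}

#' Consensus surface across scales
#'
#' Cell-wise mean of the per-scale surfaces, each first rescaled to [0, 1]
#' by its own maximum; all-zero surfaces are skipped with a warning.
#'
#' @param surfaces list of `aoe_surface` over different radii (shared grid)
#' @return raster_grid with values in [0, 1]
#' @export
gie_consensus <- function(surfaces) {
  assert_that(length(surfaces) >= 2L, "consensus needs >= 2 scales")
  mats <- list()
  for (s in surfaces) {
    v <- values_rowmajor(s$support)
    mx <- max(v, na.rm = TRUE)
    if (mx == 0) {
      warning(sprintf("zero surface at scale R = %g skipped", s$R))
      next
    }
    mats[[length(mats) + 1L]] <- v / mx
  }
  assert_that(length(mats) >= 1L, "all scales empty")
  mean_v <- Reduce(`+`, mats) / length(mats)
  set_values_rowmajor(surfaces[[1L]]$support, mean_v)
}

# 8-connected components of a logical matrix; returns an integer matrix of
# component labels (0 = background)
connected_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(lab)
  for (s in seq_len(nrow(idx))) {
    r0 <- idx[s, 1]; c0 <- idx[s, 2]
    if (lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0L) {
      r <- queue[1, 1]; c <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || cc < 1 || rr > nrow(mask) || cc > ncol(mask)) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

#' Extract areas of endemism from a support surface
#'
#' Thresholds the surface at `threshold * max`, takes 8-connected components
#' of the super-threshold cells, attaches every species whose kernel disk
#' (centroid, radius R) reaches a component, and keeps components with at
#' least two species (endemism requires congruence).
#'
#' @param surface `aoe_surface`, or a raster_grid (e.g. a consensus) plus `R`
#' @param threshold fraction of the surface maximum in (0, 1)
#' @param summary species range summary
#' @param R kernel radius used for species membership (defaults to the
#'   surface's own scale)
#' @return data.frame of class `aoe_table` (aoe_id, n_species, species
#'   comma-joined, peak support, n_cells) with a `components` attribute
#'   holding the label raster
#' @export
extract_aoes <- function(surface, threshold = 0.5, summary, R = NULL) {
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  grid <- if (inherits(surface, "aoe_surface")) surface$support else surface
  R <- R %||% (if (inherits(surface, "aoe_surface")) surface$R else
    stop2("R required when extracting from a bare grid"))
  v <- grid$values
  mx <- max(v, na.rm = TRUE)
  empty <- structure(data.frame(aoe_id = integer(0), n_species = integer(0),
                                species = character(0), peak = numeric(0),
                                n_cells = integer(0)),
                     class = c("aoe_table", "data.frame"))
  if (!is.finite(mx) || mx == 0) return(empty)
  m <- !is.na(v) & v >= threshold * mx
  lab <- connected_components8(m)
  if (max(lab) == 0L) return(empty)
  cc <- cell_centers(grid)
  lab_rm <- as.vector(t(lab))   # row-major, matching cell_centers order
  elig <- summary[summary$r <= R, , drop = FALSE]
  rows <- list()
  keep_labels <- integer(0)
  for (comp in seq_len(max(lab))) {
    cells <- cc[lab_rm == comp, , drop = FALSE]
    members <- character(0)
    for (i in seq_len(nrow(elig))) {
      d <- sqrt((cells[, 1] - elig$cx[i])^2 + (cells[, 2] - elig$cy[i])^2)
      if (any(d <= R)) members <- c(members, elig$sp[i])
    }
    if (length(members) < 2L) next
    keep_labels <- c(keep_labels, comp)
    rows[[length(rows) + 1L]] <-
      data.frame(aoe_id = length(rows) + 1L, n_species = length(members),
                 species = paste(members, collapse = ","),
                 peak = max(v[lab == comp], na.rm = TRUE),
                 n_cells = sum(lab_rm == comp))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  relabel <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep_labels)) relabel[lab == keep_labels[i]] <- i
  attr(out, "components") <- set_values_rowmajor(grid, as.vector(t(relabel)))
  class(out) <- c("aoe_table", "data.frame")
  out
}

#' Default analysis scales from the range-size distribution
#'
#' Geometric series of `n` radii from the 10th to the 90th percentile of the
#' positive species range radii.
#'
#' @param summary species range summary
#' @param n number of scales
#' @export
gie_default_scales <- function(summary, n = 5) {
  r <- summary$r[summary$r > 0]
  assert_that(length(r) >= 1L, "no species with positive range radius")
  q <- stats::quantile(r, c(0.1, 0.9), names = FALSE)
  if (q[1] <= 0) q[1] <- min(r)
  exp(seq(log(q[1]), log(max(q[2], q[1] * 1.0001)), length.out = n))
}

#' Full multi-scale kernel endemism analysis
#'
#' @param occ occurrence_table
#' @param area study_area (mask)
#' @param target raster_grid template
#' @param radii kernel radii; default [gie_default_scales()]
#' @param threshold AoE extraction threshold (fraction of max)
#' @return list: summary, surfaces (per scale), consensus (raster_grid),
#'   aoes (aoe_table from the consensus, membership radius = max scale)
#' @export
run_gie <- function(occ, area, target, radii = NULL, threshold = 0.5) {
  summary <- species_range_summary(occ)
  radii <- radii %||% gie_default_scales(summary)
  assert_that(length(radii) >= 2L, "need >= 2 scales")
  surfaces <- lapply(radii, function(R) gie_scale(summary, R, target, area))
  consensus <- gie_consensus(surfaces)
  aoes <- extract_aoes(consensus, threshold, summary, R = max(radii))
  list(summary = summary, surfaces = surfaces, consensus = consensus,
       aoes = aoes, radii = radii, threshold = threshold)
}
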