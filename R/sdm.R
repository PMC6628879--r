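# SDM pre/post-processing: the Bioclim percentile envelope, pseudo-absence
# generators (uniform and sampling-evidence weighted), binary-map validation
# statistics, AUC, niche overlap, minimum convex hull and raster utilities.

# midpoint-convention percentile rank of q within sample v: ties count half
percentile_rank <- function(q, v) {
  n <- length(v)
  vapply(q, function(x) (sum(v < x) + 0.5 * sum(v == x)) / n, 0)
}

#' Bioclim envelope suitability model
#'
#' For each cell and each predictor band, let p be the percentile rank of
#' the cell's value within the presence sample (midpoint tie convention).
#' The band score is 2 * min(p, 1 - p) (1 at the presence median, falling to
#' 0 at the sample extremes); the cell suitability is the minimum over
#' bands, and values outside the presence min-max score 0. Constant bands
#' are skipped with a warning.
#'
#' @param presences occurrence_table of one species (>= 5 usable records)
#' @param predictors raster_stack
#' @param mask optional study_area
#' @return raster_grid with values in [0, 1]
#' @export
bioclim_envelope <- function(presences, predictors, mask = NULL) {
  X <- extract_values_to_points(occ_xy(presences), predictors)
  ok <- stats::complete.cases(X)
  assert_that(sum(ok) >= 5L, "need >= 5 presences with valid predictor values")
  X <- X[ok, , drop = FALSE]
  tmpl <- predictors$bands[[1L]]
  valid <- mask_cells(tmpl, mask)
  M <- stack_matrix(predictors)[valid, , drop = FALSE]
  suit <- rep(1, nrow(M))
  used <- 0L
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (max(v) == min(v)) {
      warning(paste0("constant predictor band skipped: ", colnames(X)[j]))
      next
    }
    used <- used + 1L
    p <- percentile_rank(M[, j], v)
    score <- 2 * pmin(p, 1 - p)
    score[M[, j] < min(v) | M[, j] > max(v)] <- 0
    suit <- pmin(suit, score)
  }
  assert_that(used >= 1L, "all predictor bands constant")
  suit[!stats::complete.cases(M)] <- NA_real_
  fill_grid(tmpl, valid, suit)
}

#' Random pseudo-absences
#'
#' Uniform points inside the study area, each at least `min_dist` from every
#' presence. Deterministic given `seed`.
#'
#' @param presences occurrence_table (or NULL for none)
#' @param area study_area
#' @param n number of points
#' @param min_dist minimum distance to any presence
#' @param seed integer seed
#' @param max_tries rejection-sampling budget multiplier
#' @return occurrence_table with species label "pseudo_absence"
#' @export
pseudo_absences_random <- function(presences, area, n, min_dist = 0,
                                   seed = 1, max_tries = 200L) {
  set.seed(seed)
  bb <- area_bbox(area)
  pres_xy <- if (is.null(presences)) NULL else occ_xy(presences)
  got_x <- numeric(0); got_y <- numeric(0)
  tries <- 0L
  while (length(got_x) < n && tries < max_tries) {
    tries <- tries + 1L
    m <- max(n * 2L, 64L)
    x <- stats::runif(m, bb["xmin"], bb["xmax"])
    y <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- area_contains(area, cbind(x, y))
    if (!is.null(pres_xy) && min_dist > 0 && any(keep)) {
      d <- cross_dist(cbind(x, y)[keep, , drop = FALSE], pres_xy)
      keep[keep] <- apply(d, 1L, min) >= min_dist
    }
    got_x <- c(got_x, x[keep]); got_y <- c(got_y, y[keep])
  }
  if (length(got_x) < n)
    stop2(sprintf("could only place %d of %d pseudo-absences", length(got_x), n))
  occurrence_table(rep("pseudo_absence", n), got_x[seq_len(n)],
                   got_y[seq_len(n)], crs = area$crs)
}

#' Sampling-evidence pseudo-absences
#'
#' Draws pseudo-absence cells with probability proportional to the sampling-
#' effort kernel density of the whole group's records, the premise being
#' that a well-sampled area without occurrences of the focal species is
#' more likely a true absence. Cells closer than `min_dist` to a focal
#' presence are ineligible; the selected cells are jittered uniformly
#' within the cell.
#'
#' @param all_records occurrence_table of the whole taxonomic group
#' @param presences occurrence_table of the focal species
#' @param area study_area
#' @param target raster_grid template for the effort map
#' @param n number of points (drawn without replacement over cells)
#' @param bandwidth kernel bandwidth for the effort map
#' @param min_dist minimum distance to focal presences
#' @param seed integer seed
#' @return occurrence_table with species label "pseudo_absence"
#' @export
pseudo_absences_evidence <- function(all_records, presences, area, target, n,
                                     bandwidth, min_dist = 0, seed = 1) {
  eff <- sampling_effort(all_records, target, area, bandwidth)
  dens <- values_rowmajor(eff)
  cc <- cell_centers(eff)
  elig <- !is.na(dens) & dens > 0
  if (!is.null(presences)) {
    d <- cross_dist(cc, occ_xy(presences))
    nearest <- apply(d, 1L, min)
    # a cell containing (or within min_dist of) a focal presence is ineligible
    elig <- elig & nearest >= max(min_dist, eff$cellsize / 2)
  }
  if (sum(elig) == 0L)
    stop2("no eligible cells: sampling density is zero outside the presence buffer")
  assert_that(sum(elig) >= n,
              sprintf("only %d eligible cells for %d draws", sum(elig), n))
  set.seed(seed)
  idx <- sample(which(elig), n, prob = dens[elig])
  half <- eff$cellsize / 2
  x <- cc[idx, 1] + stats::runif(n, -half, half)
  y <- cc[idx, 2] + stats::runif(n, -half, half)
  occurrence_table(rep("pseudo_absence", n), x, y, crs = area$crs)
}

#' Validation statistics for a binary prediction map
#'
#' Points are matched to prediction cells by cell-center containment; points
#' on nodata cells are dropped and counted. Statistics with a zero
#' denominator are reported NA, never 0.
#'
#' @param obs data.frame with columns x, y, obs (0/1)
#' @param pred binary raster_grid
#' @return list: counts (tp, fp, fn, tn, n_dropped), accuracy, precision,
#'   sensitivity, specificity, kappa, tss
#' @export
validate_binary <- function(obs, pred) {
  loc <- locate_cells(pred, cbind(obs$x, obs$y))
  ok <- !is.na(loc$value)
  n_dropped <- sum(!ok)
  assert_that(any(ok), "no observation falls on a valid prediction cell")
  p <- loc$value[ok]; o <- obs$obs[ok]
  assert_that(all(p %in% c(0, 1)), "prediction raster is not binary")
  tp <- sum(o == 1 & p == 1); fp <- sum(o == 0 & p == 1)
  fn <- sum(o == 1 & p == 0); tn <- sum(o == 0 & p == 0)
  confusion_stats(tp, fp, fn, tn, n_dropped)
}

#' Statistics from explicit confusion counts
#' @param tp,fp,fn,tn confusion counts
#' @param n_dropped points dropped before counting (reported back)
#' @return list as in [validate_binary()]
#' @export
confusion_stats <- function(tp, fp, fn, tn, n_dropped = 0L) {
  n <- tp + fp + fn + tn
  assert_that(n >= 1, "empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  p0 <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (p0 - pe) / (1 - pe)
  list(counts = list(tp = tp, fp = fp, fn = fn, tn = tn,
                     n_dropped = n_dropped),
       accuracy = p0,
       precision = ratio(tp, tp + fp),
       sensitivity = sens,
       specificity = spec,
       kappa = kappa,
       tss = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC = (number of concordant positive/negative score pairs + half the
#' ties) / (n_pos * n_neg), computed via midranks.
#'
#' @param obs 0/1 labels
#' @param score continuous scores (same length)
#' @return AUC in [0, 1]
#' @export
auc_score <- function(obs, score) {
  assert_that(length(obs) == length(score), "obs and score lengths differ")
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) stop2("AUC undefined: one class is empty")
  r <- rank(score)
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a continuous raster against labeled points
#' @param obs data.frame with x, y, obs (0/1)
#' @param score_grid raster_grid of continuous scores
#' @export
auc_raster <- function(obs, score_grid) {
  loc <- locate_cells(score_grid, cbind(obs$x, obs$y))
  ok <- !is.na(loc$value)
  auc_score(obs$obs[ok], loc$value[ok])
}

#' Niche overlap between two suitability rasters
#'
#' Both rasters are normalized to sum 1 over their shared valid cells;
#' Schoener's D = 1 - sum|pa - pb| / 2 and the Hellinger-based
#' I = 1 - sum((sqrt(pa) - sqrt(pb))^2) / 2.
#'
#' @param sa,sb aligned raster_grid suitability maps
#' @return named vector (D, I)
#' @export
niche_overlap <- function(sa, sb) {
  assert_that(same_geometry(sa, sb), "rasters are not aligned")
  va <- values_rowmajor(sa); vb <- values_rowmajor(sb)
  ok <- !is.na(va) & !is.na(vb)
  sa_sum <- sum(va[ok]); sb_sum <- sum(vb[ok])
  if (sa_sum <= 0 || sb_sum <= 0) stop2("zero-sum raster cannot be normalized")
  pa <- va[ok] / sa_sum; pb <- vb[ok] / sb_sum
  c(D = 1 - 0.5 * sum(abs(pa - pb)),
    I = 1 - 0.5 * sum((sqrt(pa) - sqrt(pb))^2))
}

#' Minimum convex hull of a species' records
#'
#' @param occ occurrence_table
#' @param species species label (default: use all records)
#' @return list: `polygon` (closed coordinate matrix), `area`
#' @export
minimum_convex_hull <- function(occ, species = NULL) {
  xy <- occ_xy(occ)
  if (!is.null(species)) xy <- xy[occ$sp == species, , drop = FALSE]
  xy <- unique(xy)
  if (nrow(xy) < 3L) stop2("convex hull needs >= 3 distinct points")
  h <- grDevices::chull(xy[, 1], xy[, 2])
  ring <- close_ring(xy[h, , drop = FALSE])
  a <- abs(shoelace(ring))
  if (a <= 0) stop2("degenerate hull: points are collinear")
  list(polygon = ring, area = a)
}

#' Regular sample points from a binary map or polygon
#'
#' Lays a regular square lattice over the source, clipped to presence cells
#' (or the polygon), with the pitch chosen so the retained count is as close
#' to `n` as possible from above; the exact count `n` is then met by
#' dropping points from the lattice tail. Sources too small for the lattice
#' fall back to the single centroid with a warning.
#'
#' @param source binary raster_grid or study_area
#' @param n number of points
#' @param species label to assign
#' @return occurrence_table
#' @export
create_sample_points <- function(source, n, species = "sample") {
  inside <- function(xy) {
    if (inherits(source, "study_area")) area_contains(source, xy)
    else {
      v <- locate_cells(source, xy)$value
      !is.na(v) & v == 1
    }
  }
  bb <- if (inherits(source, "study_area")) area_bbox(source) else
    c(xmin = source$xmin, ymin = source$ymin,
      xmax = source$xmin + n_cols(source) * source$cellsize,
      ymax = source$ymin + n_rows(source) * source$cellsize)
  span_x <- bb["xmax"] - bb["xmin"]; span_y <- bb["ymax"] - bb["ymin"]
  # effective source area for the initial pitch guess
  a0 <- if (inherits(source, "study_area")) area_of(source) else
    sum(source$values == 1, na.rm = TRUE) * source$cellsize^2
  if (a0 <= 0) stop2("source has no positive area")
  lattice <- function(pitch) {
    xs <- seq(bb["xmin"] + pitch / 2, bb["xmax"], by = pitch)
    ys <- seq(bb["ymin"] + pitch / 2, bb["ymax"], by = pitch)
    xy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    xy[inside(xy), , drop = FALSE]
  }
  pitch <- sqrt(a0 / n)
  pts <- lattice(pitch)
  it <- 0L
  while (nrow(pts) < n && it < 40L) {
    pitch <- pitch * 0.9
    pts <- lattice(pitch)
    it <- it + 1L
  }
  if (nrow(pts) == 0L || (nrow(pts) < n && pitch < 1e-9 * max(span_x, span_y))) {
    warning("source smaller than one lattice node; falling back to centroid")
    ctr <- cbind(mean(bb[c("xmin", "xmax")]), mean(bb[c("ymin", "ymax")]))
    return(occurrence_table(species, ctr[1], ctr[2]))
  }
  if (nrow(pts) < n) {
    warning(sprintf("placed %d of %d requested points", nrow(pts), n))
    n <- nrow(pts)
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  occurrence_table(rep(species, n), pts[, 1], pts[, 2])
}

# --- raster utilities -------------------------------------------------------

#' Extract raster-stack values at point locations
#' @param xy two-column coordinate matrix (or data.frame with x, y)
#' @param stack raster_stack
#' @return data.frame, one column per band; NA for off-grid/nodata points
#' @export
extract_values_to_points <- function(xy, stack) {
  if (is.data.frame(xy)) xy <- cbind(xy$x, xy$y)
  out <- lapply(stack$bands, function(g) locate_cells(g, xy)$value)
  as.data.frame(out)
}

#' Cell-wise sum of stack bands
#' @param stack raster_stack
#' @param require_all when TRUE a cell is valid only if every band is valid;
#'   default: valid when at least one band is valid (nodata ignored)
#' @return raster_grid
#' @export
sum_of_maps <- function(stack, require_all = FALSE) {
  M <- stack_matrix(stack)
  s <- rowSums(M, na.rm = !require_all)
  none <- rowSums(!is.na(M)) == 0L
  s[none] <- NA_real_
  set_values_rowmajor(stack$bands[[1L]], s)
}

#' Area of a binary distribution map
#' @param grid binary raster_grid
#' @return presence-cell count times cell area
#' @export
area_of_distribution <- function(grid) {
  v <- values_rowmajor(grid)
  assert_that(all(v[!is.na(v)] %in% c(0, 1)), "raster is not binary")
  sum(v == 1, na.rm = TRUE) * grid$cellsize^2
}

#' Min-max rescale a raster to [0, 1]
#' @param grid raster_grid
#' @return raster_grid of class-compatible values in [0, 1]
#' @export
rescale01 <- function(grid) {
  v <- values_rowmajor(grid)
  rng <- range(v, na.rm = TRUE)
  if (rng[1] == rng[2]) stop2("constant raster cannot be rescaled")
  set_values_rowmajor(grid, (v - rng[1]) / (rng[2] - rng[1]))
}
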