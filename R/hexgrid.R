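# Equal-area hexagonal sample units. Flat-topped hexagons of side s anchored
# at the mask bounding-box lower-left corner; centers form a lattice with
# horizontal pitch 1.5 s and vertical pitch sqrt(3) s (odd columns shifted up
# by half a pitch). Each hexagon has area (3*sqrt(3)/2) s^2.

hex_vertices <- function(cx, cy, side) {
  ang <- (0:5) * pi / 3
  cbind(cx + side * cos(ang), cy + side * sin(ang))
}

# point-in-flat-top-hexagon test, hexagon centered at (cx, cy)
in_hex <- function(px, py, cx, cy, side, tol = 1e-9) {
  q <- abs(px - cx); r <- abs(py - cy)
  h <- sqrt(3) / 2 * side
  r <= h + tol & sqrt(3) * q + r <= sqrt(3) * side + tol
}

#' Build an equal-area hexagonal grid over a study area
#'
#' @param area study_area
#' @param side hexagon edge length (map units)
#' @return object of class `hex_grid` with fields `cell_id`, `centers`,
#'   `side`, `crs`; only cells intersecting the mask are retained
#' @export
build_hex_grid <- function(area, side) {
  assert_that(side > 0, "side must be > 0")
  bb <- area_bbox(area)
  assert_that(side < max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"]),
              "hexagon side exceeds the study-area extent")
  dx <- 1.5 * side
  dy <- sqrt(3) * side
  ncol_hex <- ceiling((bb["xmax"] - bb["xmin"]) / dx) + 2L
  nrow_hex <- ceiling((bb["ymax"] - bb["ymin"]) / dy) + 2L
  cols <- seq_len(ncol_hex) - 1L
  rows <- seq_len(nrow_hex) - 1L
  cx <- bb["xmin"] + rep(cols, each = length(rows)) * dx
  cy <- bb["ymin"] + rep(rows, times = length(cols)) * dy +
    rep(cols %% 2, each = length(rows)) * dy / 2
  centers <- cbind(x = cx, y = cy)

  # retain cells that intersect the mask: sampled on center, vertices, edge
  # midpoints, or any mask vertex falling inside the hexagon
  keep <- logical(nrow(centers))
  mask_pts <- do.call(rbind, lapply(area$polygons, function(p)
    do.call(rbind, p)))
  for (i in seq_len(nrow(centers))) {
    v <- hex_vertices(centers[i, 1], centers[i, 2], side)
    mids <- (v + v[c(2:6, 1), ]) / 2
    probe <- rbind(centers[i, , drop = FALSE], v, mids)
    if (any(area_contains(area, probe))) { keep[i] <- TRUE; next }
    keep[i] <- any(in_hex(mask_pts[, 1], mask_pts[, 2],
                          centers[i, 1], centers[i, 2], side))
  }
  if (sum(keep) < 1L) stop2("degenerate grid: no hexagon intersects the mask")
  centers <- centers[keep, , drop = FALSE]
  ord <- order(centers[, 2], centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  structure(list(cell_id = seq_len(nrow(centers)), centers = centers,
                 side = side, crs = area$crs),
            class = "hex_grid")
}

#' Hexagon cell area of a grid
#' @param grid hex_grid
#' @export
hex_cell_area <- function(grid) 3 * sqrt(3) / 2 * grid$side^2

#' Polygons of a hex grid as a GeoJSON FeatureCollection file
#' @param grid hex_grid
#' @param path output path
#' @export
write_hex_grid <- function(grid, path) {
  feats <- lapply(seq_along(grid$cell_id), function(i) {
    v <- hex_vertices(grid$centers[i, 1], grid$centers[i, 2], grid$side)
    v <- rbind(v, v[1, ])
    list(type = "Feature",
         properties = list(cell_id = grid$cell_id[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(v)),
                                                   function(k) c(v[k, 1], v[k, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# map points to hexagon cells; NA for points in no retained cell.
# Nearest-center assignment is exact for a hexagonal tiling; ties on shared
# edges resolve to the smaller cell_id (centers are scanned in id order).
hex_assign <- function(grid, xy) {
  xy <- as.matrix(xy)
  d <- cross_dist(xy, grid$centers)
  nearest <- apply(d, 1L, which.min)  # which.min takes the first (smallest id)
  ok <- in_hex(xy[, 1], xy[, 2],
               grid$centers[nearest, 1], grid$centers[nearest, 2], grid$side)
  out <- grid$cell_id[nearest]
  out[!ok] <- NA_integer_
  out
}

#' Build a community matrix from occurrences on a hex grid
#'
#' Each record is assigned to the unique hexagon containing it; records
#' falling in no retained cell are dropped and counted. Species absent from
#' every cell are dropped with a warning.
#'
#' @param occ occurrence_table
#' @param grid hex_grid
#' @return object of class `community_matrix`: `sites` (cell ids), `species`,
#'   `incidence` and `n_records` (site x species), `site_xy` (cell centers),
#'   `n_dropped` (records outside the grid)
#' @export
assign_points <- function(occ, grid) {
  cells <- hex_assign(grid, occ_xy(occ))
  dropped <- sum(is.na(cells))
  if (dropped > 0)
    message(sprintf("%d point(s) outside the study area are ignored", dropped))
  keep <- !is.na(cells)
  if (!any(keep)) stop2("no occurrence point falls inside the grid")
  tab <- table(factor(cells[keep], levels = grid$cell_id), occ$sp[keep])
  n_rec <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
  empty_sp <- colSums(n_rec) == 0L
  if (any(empty_sp)) {
    warning(sprintf("%d species outside all sites dropped", sum(empty_sp)))
    n_rec <- n_rec[, !empty_sp, drop = FALSE]
  }
  # empty sites (cells without records) are retained: richness there is 0,
  # indices with stricter preconditions report them as missing
  structure(list(sites = grid$cell_id,
                 species = colnames(n_rec),
                 incidence = (n_rec >= 1L) * 1L,
                 n_records = n_rec,
                 site_xy = grid$centers,
                 n_dropped = dropped,
                 side = grid$side),
            class = "community_matrix")
}

#' Build a community matrix from per-species binary rasters
#'
#' @param stack raster_stack of {0,1} bands, band names = species labels
#' @param grid hex_grid
#' @param rule `"any"`: a species is present in a cell when at least one of
#'   its presence pixels falls there; `"majority"`: when more than half of
#'   the cell's valid pixels are presences
#' @return community_matrix (n_records counts presence pixels per cell)
#' @export
community_from_binary_stack <- function(stack, grid, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  for (nm in band_names(stack)) {
    v <- values_rowmajor(stack$bands[[nm]])
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop2(paste0("non-binary values in band: ", nm))
  }
  cc <- cell_centers(stack$bands[[1L]])
  cell <- hex_assign(grid, cc)
  n_sp <- n_bands(stack)
  counts <- matrix(0L, length(grid$cell_id), n_sp,
                   dimnames = list(grid$cell_id, band_names(stack)))
  valid_px <- matrix(0L, length(grid$cell_id), n_sp,
                     dimnames = dimnames(counts))
  ok <- !is.na(cell)
  fcell <- factor(cell[ok], levels = grid$cell_id)
  for (j in seq_len(n_sp)) {
    v <- values_rowmajor(stack$bands[[j]])[ok]
    counts[, j] <- as.integer(tapply(v, fcell, function(z) sum(z == 1, na.rm = TRUE),
                                     default = 0))
    valid_px[, j] <- as.integer(tapply(v, fcell, function(z) sum(!is.na(z)),
                                       default = 0))
  }
  pres <- if (rule == "any") counts >= 1L else
    valid_px > 0L & counts > valid_px / 2
  empty_sp <- colSums(pres) == 0L
  if (any(empty_sp))
    warning(sprintf("%d species present in no cell dropped", sum(empty_sp)))
  pres <- pres[, !empty_sp, drop = FALSE]
  counts <- counts[, !empty_sp, drop = FALSE]
  assert_that(any(pres), "no species present in any cell")
  structure(list(sites = grid$cell_id,
                 species = colnames(pres),
                 incidence = pres * 1L,
                 n_records = counts * (pres * 1L),
                 site_xy = grid$centers,
                 n_dropped = sum(!ok),
                 side = grid$side),
            class = "community_matrix")
}

#' Write a community matrix as wide CSV (rows = cell_id, cols = species)
#' @param cm community_matrix
#' @param path output path
#' @export
write_community <- function(cm, path) {
  df <- data.frame(cell_id = cm$sites, cm$incidence, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species, %d records (%d dropped)\n",
              length(x$sites), length(x$species), sum(x$n_records), x$n_dropped))
  invisible(x)
}
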