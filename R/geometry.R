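# Planar polygon support. Polygons are lists of rings; each ring is a closed
# two-column coordinate matrix (first ring = outer boundary, others = holes).
# All computation is planar: inputs in geographic degrees are flagged once and
# distances are then degree-space distances unless the user reprojects.

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Create a study area from polygon rings
#'
#' @param polygons list of polygons; each polygon is a list of rings (closed
#'   two-column matrices), the first ring being the outer boundary and the
#'   remainder holes
#' @param crs coordinate tag; `"degrees"` flags planar-on-degrees computation
#' @return object of class `study_area`
#' @export
study_area <- function(polygons, crs = "planar") {
  polygons <- lapply(polygons, function(p) lapply(p, close_ring))
  for (p in polygons) for (r in p)
    assert_that(nrow(r) >= 4L, "a polygon ring needs at least 3 distinct vertices")
  a <- sum(vapply(polygons, function(p) {
    abs(shoelace(p[[1]])) - sum(vapply(p[-1], function(h) abs(shoelace(h)), 0))
  }, 0))
  assert_that(a > 0, "study area has zero area")
  if (identical(crs, "degrees"))
    message("coordinates are geographic degrees; distances are degree-space")
  structure(list(polygons = polygons, crs = crs), class = "study_area")
}

#' Rectangular study area helper
#' @param xmin,ymin,xmax,ymax rectangle corners
#' @inheritParams study_area
#' @export
study_area_rect <- function(xmin, ymin, xmax, ymax, crs = "planar") {
  ring <- cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin))
  study_area(list(list(ring)), crs = crs)
}

#' Total area of a study area (outer rings minus holes)
#' @param area study_area
#' @export
area_of <- function(area) {
  sum(vapply(area$polygons, function(p) {
    abs(shoelace(p[[1]])) - sum(vapply(p[-1], function(h) abs(shoelace(h)), 0))
  }, 0))
}

#' Bounding box of a study area
#' @param area study_area
#' @return named vector xmin, ymin, xmax, ymax
#' @export
area_bbox <- function(area) {
  pts <- do.call(rbind, lapply(area$polygons, function(p) do.call(rbind, p)))
  c(xmin = min(pts[, 1]), ymin = min(pts[, 2]),
    xmax = max(pts[, 1]), ymax = max(pts[, 2]))
}

# even-odd ray casting for one ring; boundary points count as inside
ring_contains <- function(ring, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  inside <- logical(length(x))
  n <- nrow(ring) - 1L
  xi <- ring[, 1]; yi <- ring[, 2]
  for (i in seq_len(n)) {
    x1 <- xi[i]; y1 <- yi[i]; x2 <- xi[i + 1L]; y2 <- yi[i + 1L]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Test which points fall inside a study area
#' @param area study_area
#' @param xy two-column matrix of points
#' @return logical vector
#' @export
area_contains <- function(area, xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) == 0L) return(logical(0))
  res <- logical(nrow(xy))
  for (p in area$polygons) {
    inp <- ring_contains(p[[1]], xy)
    for (h in p[-1]) inp <- inp & !ring_contains(h, xy)
    res <- res | inp
  }
  res
}

geojson_poly_rings <- function(coords, flag = NULL) {
  lapply(coords, function(ring) {
    m <- if (is.matrix(ring)) ring else do.call(rbind, lapply(ring, unlist))
    m <- m[, 1:2, drop = FALSE]
    if (!all(m[1, ] == m[nrow(m), ]) && is.environment(flag))
      flag$open <- TRUE
    close_ring(m)
  })
}

#' Read a study-area mask from GeoJSON
#'
#' Accepts Polygon and MultiPolygon geometries (bare, Feature, or
#' FeatureCollection). Unclosed rings are auto-closed with a warning;
#' degenerate rings (fewer than 3 distinct vertices) raise an error.
#'
#' @param path GeoJSON file
#' @param crs coordinate tag attached to the result
#' @return study_area merging all polygons found
#' @export
read_mask <- function(path, crs = "planar") {
  assert_that(file.exists(path), paste0("no such file: ", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  geoms <- list()
  push_geom <- function(g) geoms[[length(geoms) + 1L]] <<- g
  collect <- function(obj) {
    type <- obj$type %||% stop2("GeoJSON object without type")
    if (type == "FeatureCollection") {
      feats <- obj$features
      if (is.data.frame(feats)) {
        for (i in seq_len(nrow(feats))) {
          collect(list(type = "Feature",
                       geometry = list(type = feats$geometry$type[i],
                                       coordinates = feats$geometry$coordinates[[i]])))
        }
      } else for (f in feats) collect(f)
    } else if (type == "Feature") {
      collect(obj$geometry)
    } else if (type %in% c("Polygon", "MultiPolygon")) {
      push_geom(obj)
    } else {
      stop2(paste0("unsupported geometry type for a mask: ", type))
    }
  }
  collect(js)
  assert_that(length(geoms) >= 1L, "no polygon geometry in file")
  flag <- new.env(); flag$open <- FALSE
  polys <- list()
  for (g in geoms) {
    co <- g$coordinates
    if (g$type == "Polygon") {
      rings <- if (is.array(co) && length(dim(co)) == 3L)
        lapply(seq_len(dim(co)[1]), function(i) co[i, , ]) else co
      polys[[length(polys) + 1L]] <- geojson_poly_rings(rings, flag)
    } else { # MultiPolygon
      parts <- if (is.array(co) && length(dim(co)) == 4L)
        lapply(seq_len(dim(co)[1]), function(i)
          lapply(seq_len(dim(co)[2]), function(j) co[i, j, , ])) else co
      for (p in parts) {
        rings <- if (is.array(p) && length(dim(p)) == 3L)
          lapply(seq_len(dim(p)[1]), function(i) p[i, , ]) else p
        polys[[length(polys) + 1L]] <- geojson_poly_rings(rings, flag)
      }
    }
  }
  if (flag$open) warning("unclosed ring(s) auto-closed")
  study_area(polys, crs = crs)
}

#' Write a study area (or any polygon list) as GeoJSON
#' @param area study_area
#' @param path output path
#' @export
write_mask <- function(area, path) {
  mp <- lapply(area$polygons, function(p)
    lapply(p, function(r) lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))))
  obj <- list(type = "MultiPolygon", coordinates = mp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("study_area: %d polygon(s), area %g (%s)\n",
              length(x$polygons), area_of(x), x$crs))
  invisible(x)
}
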