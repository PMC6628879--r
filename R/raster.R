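# Regular georeferenced grids. Values live in an nrows x ncols matrix whose
# first row is the NORTHERN edge (map orientation); cells are square with a
# single cellsize, the layout of the ESRI ASCII grid interchange format used
# for file I/O. Missing cells are NA in memory and the nodata sentinel on disk.

#' Create a raster grid
#'
#' @param values numeric matrix (nrows x ncols), row 1 = top (north); NA = nodata
#' @param xmin,ymin coordinates of the lower-left corner of the grid extent
#' @param cellsize side length of the square cells
#' @param nodata sentinel written to file for NA cells
#' @param crs free-form coordinate reference tag
#' @return object of class `raster_grid`
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        nodata = -9999, crs = "planar") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(cellsize > 0, "cellsize must be > 0")
  assert_that(all(dim(values) >= 1L), "grid must have at least one cell")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize,
         nodata = nodata, crs = crs),
    class = "raster_grid"
  )
}

#' Create an empty raster template over an extent
#'
#' @param xmin,ymin,xmax,ymax extent; the extent is expanded northward/eastward
#'   to a whole number of cells
#' @param cellsize cell side
#' @inheritParams raster_grid
#' @return `raster_grid` filled with NA
#' @export
raster_template <- function(xmin, ymin, xmax, ymax, cellsize, crs = "planar") {
  assert_that(xmax > xmin && ymax > ymin, "empty extent")
  nc <- max(1L, ceiling((xmax - xmin) / cellsize - 1e-9))
  nr <- max(1L, ceiling((ymax - ymin) / cellsize - 1e-9))
  raster_grid(matrix(NA_real_, nr, nc), xmin, ymin, cellsize, crs = crs)
}

n_rows <- function(g) nrow(g$values)
n_cols <- function(g) ncol(g$values)
y_max <- function(g) g$ymin + n_rows(g) * g$cellsize

#' Cell-center coordinates of every cell, in row-major (top-left first) order
#' @param g raster_grid
#' @return two-column matrix (x, y)
#' @export
cell_centers <- function(g) {
  xs <- g$xmin + (seq_len(n_cols(g)) - 0.5) * g$cellsize
  ys <- y_max(g) - (seq_len(n_rows(g)) - 0.5) * g$cellsize
  cbind(x = rep(xs, times = n_rows(g)),
        y = rep(ys, each = n_cols(g)))
}

# matrix values in the same row-major order as cell_centers()
values_rowmajor <- function(g) as.vector(t(g$values))

set_values_rowmajor <- function(g, v) {
  g$values <- matrix(v, n_rows(g), n_cols(g), byrow = TRUE)
  g
}

#' Locate points on a grid
#' @param g raster_grid
#' @param xy two-column matrix of coordinates
#' @return data.frame with row, col (NA when off-grid) and cell value
#' @export
locate_cells <- function(g, xy) {
  xy <- as.matrix(xy)
  col <- floor((xy[, 1] - g$xmin) / g$cellsize) + 1
  row <- floor((y_max(g) - xy[, 2]) / g$cellsize) + 1
  off <- col < 1 | col > n_cols(g) | row < 1 | row > n_rows(g)
  col[off] <- NA; row[off] <- NA
  val <- rep(NA_real_, nrow(xy))
  ok <- !off
  val[ok] <- g$values[cbind(row[ok], col[ok])]
  data.frame(row = row, col = col, value = val)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path (.asc)
#' @param crs coordinate tag to attach
#' @return raster_grid
#' @export
read_ascii_grid <- function(path, crs = "planar") {
  assert_that(file.exists(path), paste0("no such file: ", path))
  head_lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head_lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  named <- stats::setNames(vals, keys)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys) || anyNA(named[need]))
    stop2(paste0("not an ASCII grid (missing header): ", path))
  n_header <- if ("nodata_value" %in% keys) 6L else 5L
  nodata <- if ("nodata_value" %in% keys) named[["nodata_value"]] else -9999
  vals <- scan(path, skip = n_header, quiet = TRUE)
  nr <- as.integer(named[["nrows"]]); nc <- as.integer(named[["ncols"]])
  assert_that(length(vals) == nr * nc, "cell count does not match header")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, named[["xllcorner"]], named[["yllcorner"]],
              named[["cellsize"]], nodata = nodata, crs = crs)
}

#' Write an ESRI ASCII grid
#' @param g raster_grid
#' @param path output path (.asc); parent directory must exist
#' @export
write_ascii_grid <- function(g, path) {
  assert_that(dir.exists(dirname(path)),
              paste0("parent directory does not exist: ", dirname(path)))
  m <- g$values
  m[is.na(m)] <- g$nodata
  header <- c(
    paste("ncols", n_cols(g)), paste("nrows", n_rows(g)),
    paste("xllcorner", format(g$xmin, digits = 15)),
    paste("yllcorner", format(g$ymin, digits = 15)),
    paste("cellsize", format(g$cellsize, digits = 15)),
    paste("NODATA_value", format(g$nodata, digits = 15))
  )
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

same_geometry <- function(a, b, tol = 1e-9) {
  n_rows(a) == n_rows(b) && n_cols(a) == n_cols(b) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Create a raster stack from aligned grids
#' @param grids named list of `raster_grid` objects sharing geometry
#' @return object of class `raster_stack`
#' @export
raster_stack <- function(grids) {
  assert_that(length(grids) >= 1L, "stack needs at least one band")
  if (is.null(names(grids)) || any(!nzchar(names(grids))))
    names(grids) <- paste0("band", seq_along(grids))
  ref <- grids[[1L]]
  for (g in grids)
    assert_that(same_geometry(ref, g), "all bands must share grid geometry")
  structure(list(bands = grids), class = "raster_stack")
}

band_names <- function(s) names(s$bands)
n_bands <- function(s) length(s$bands)

#' Stack values as a cell x band matrix (row-major cell order)
#' @param s raster_stack
#' @export
stack_matrix <- function(s) {
  do.call(cbind, lapply(s$bands, values_rowmajor))
}

#' Read every .asc file of a directory as an aligned stack
#' @param dir directory holding .asc band files (band name = file stem)
#' @export
read_stack_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  assert_that(length(files) >= 1L, paste0("no .asc files in ", dir))
  grids <- lapply(files, read_ascii_grid)
  names(grids) <- sub("\\.asc$", "", basename(files))
  raster_stack(grids)
}

#' Write each band of a stack as <name>.asc in a directory
#' @param s raster_stack
#' @param dir output directory (created if missing)
#' @export
write_stack_dir <- function(s, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in band_names(s))
    write_ascii_grid(s$bands[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g, origin (%g, %g), %d valid\n",
              n_rows(x), n_cols(x), x$cellsize, x$xmin, x$ymin,
              sum(!is.na(x$values))))
  invisible(x)
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d band(s): %s\n", n_bands(x),
              paste(band_names(x), collapse = ", ")))
  invisible(x)
}
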