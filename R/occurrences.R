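# Occurrence tables: species-labelled points, columns sp/x/y in any order and
# case; malformed rows are dropped with a warning, never silently.

#' Create an occurrence table
#' @param sp character species labels
#' @param x,y numeric coordinates
#' @param crs coordinate tag (`"degrees"` flags planar-on-degrees computation)
#' @return data.frame of class `occurrence_table` with columns sp, x, y
#' @export
occurrence_table <- function(sp, x, y, crs = "planar") {
  sp <- as.character(sp); x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(sp) == length(x) && length(x) == length(y),
              "sp, x, y must have equal length")
  assert_that(length(sp) >= 1L, "occurrence table needs at least one record")
  assert_that(!anyNA(sp) && all(nzchar(sp)), "missing species labels")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "non-finite coordinates")
  out <- data.frame(sp = sp, x = x, y = y, stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup))
    warning(sprintf("%d duplicate (sp,x,y) record(s) retained", sum(dup)))
  attr(out, "crs") <- crs
  class(out) <- c("occurrence_table", class(out))
  out
}

#' Read species occurrences from delimited text
#'
#' Requires columns sp, x, y (case-insensitive, any order; extra columns
#' ignored). Rows with unparseable coordinates or empty species labels are
#' dropped and counted in a warning.
#'
#' @param path file path
#' @param delimiter field delimiter (default comma)
#' @param crs coordinate tag
#' @return occurrence_table
#' @export
read_occurrences <- function(path, delimiter = ",", crs = "planar") {
  assert_that(file.exists(path), paste0("no such file: ", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  nms <- tolower(names(df))
  for (col in c("sp", "x", "y"))
    if (!col %in% nms)
      stop2(paste0("missing required column: ", col))
  sp <- as.character(df[[which(nms == "sp")[1]]])
  x <- suppressWarnings(as.numeric(df[[which(nms == "x")[1]]]))
  y <- suppressWarnings(as.numeric(df[[which(nms == "y")[1]]]))
  ok <- !is.na(sp) & nzchar(sp) & is.finite(x) & is.finite(y)
  if (sum(ok) == 0L) stop2("no valid occurrence rows in file")
  if (any(!ok))
    warning(sprintf("dropped %d malformed row(s)", sum(!ok)))
  occurrence_table(sp[ok], x[ok], y[ok], crs = crs)
}

#' Write an occurrence table as CSV (columns sp,x,y)
#' @param occ occurrence_table
#' @param path output path
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("sp", "x", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

occ_xy <- function(occ) cbind(occ$x, occ$y)

#' Read a rooted phylogeny from a newick file
#'
#' @param path newick file
#' @param allow_unit_lengths when the tree lacks branch lengths, set all
#'   lengths to 1 with a warning instead of failing
#' @return `ape::phylo` tree with branch lengths
#' @export
read_tree <- function(path, allow_unit_lengths = FALSE) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    stop2(sprintf("newick parse error: %d '(' vs %d ')'", n_open, n_close))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop2(paste0("newick parse error: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) stop2("newick parse error: unreadable tree")
  if (is.null(tree$edge.length)) {
    if (!allow_unit_lengths)
      stop2("tree has no branch lengths (set allow_unit_lengths = TRUE to use 1)")
    warning("tree has no branch lengths; all set to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  assert_that(all(tree$edge.length >= 0), "negative branch length")
  assert_that(!anyDuplicated(tree$tip.label), "duplicate tip labels")
  tree
}
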