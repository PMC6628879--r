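#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

#' Pairwise Euclidean distances between two point sets
#' @param a,b two-column matrices of coordinates
#' @return |a| x |b| distance matrix
#' @keywords internal
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Adjusted Rand Index between two labelings
#'
#' Agreement between two partitions of the same items, corrected for chance;
#' 1 means identical partitions (up to relabeling), 0 is the chance level.
#'
#' @param a,b integer or factor label vectors of equal length
#' @return scalar ARI
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# derive a reproducible child seed (< 2^31) from a base seed and a tag
child_seed <- function(seed, tag) {
  (as.integer(seed) * 7919L + as.integer(tag) * 104729L) %% 2147483629L
}
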