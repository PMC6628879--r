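# Shared fixture builders. Everything is generated in code at test time;
# files are written to tempdir() only.

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# unit square GeoJSON polygon [0,1]x[0,1]
unit_square_geojson <- function() {
  write_tmp(paste0(
    '{"type":"Polygon","coordinates":[[[0,0],[1,0],[1,1],[0,1],[0,0]]]}'),
    ".geojson")
}

two_squares_geojson <- function() {
  write_tmp(paste0(
    '{"type":"MultiPolygon","coordinates":[',
    '[[[0,0],[1,0],[1,1],[0,1],[0,0]]],',
    '[[[2,0],[3,0],[3,1],[2,1],[2,0]]]]}'), ".geojson")
}

# the 3-tip reference tree used across phylogenetic tests
ref_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# small community matrix built directly (bypassing the grid) for index tests
make_cm <- function(incidence, n_records = NULL, site_xy = NULL) {
  incidence <- as.matrix(incidence)
  rownames(incidence) <- seq_len(nrow(incidence))
  if (is.null(colnames(incidence)))
    colnames(incidence) <- paste0("sp", seq_len(ncol(incidence)))
  if (is.null(n_records)) n_records <- incidence
  if (is.null(site_xy))
    site_xy <- cbind(seq_len(nrow(incidence)), 0)
  structure(list(sites = as.integer(rownames(incidence)),
                 species = colnames(incidence),
                 incidence = incidence * 1L,
                 n_records = as.matrix(n_records),
                 site_xy = site_xy, n_dropped = 0L, side = 1),
            class = "community_matrix")
}

# brute-force AUC over all positive x negative pairs (independent oracle)
auc_bruteforce <- function(obs, score) {
  pos <- score[obs == 1]; neg <- score[obs == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random community + random tree pair for conservation identities
random_community_tree <- function(n_sites, n_species, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_species)
  inc <- matrix(rbinom(n_sites * n_species, 1, 0.4), n_sites, n_species,
                dimnames = list(seq_len(n_sites), tree$tip.label))
  # ensure no empty species column (they would be undefined in WE)
  for (j in which(colSums(inc) == 0)) inc[sample(n_sites, 1), j] <- 1L
  list(cm = make_cm(inc), tree = tree)
}
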