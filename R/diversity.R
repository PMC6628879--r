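# Alpha, beta and phylogenetic diversity on incidence community matrices.
#
# Conventions:
#  * sites with no species get a missing (NA) value for indices undefined
#    there, never a silent 0 (richness itself is legitimately 0);
#  * Faith PD is rooted: the path to the root is part of every site's
#    spanning subtree, so a single-tip site has nonzero PD and PE equals PD
#    whenever a site is the sole occupant of its branches;
#  * the beta family is the Sorensen partition: turnover is the Simpson
#    component, nestedness the Sorensen - Simpson remainder.

site_index_table <- function(cm, value, index, parameters = list()) {
  structure(data.frame(cell_id = cm$sites, value = value),
            index = index, parameters = parameters,
            class = c("site_index_table", "data.frame"))
}

#' Species richness per site
#' @param cm community_matrix
#' @return site_index_table (cell_id, value)
#' @export
richness <- function(cm) {
  site_index_table(cm, as.numeric(rowSums(cm$incidence)), "richness")
}

#' Rarefied species richness per site
#'
#' Mean species count over `reps` uniform without-replacement draws of `n`
#' records from each site's record pool; sites with fewer than `n` records
#' are reported missing.
#'
#' @param cm community_matrix
#' @param n subsample size (records)
#' @param reps number of draws
#' @param seed integer seed
#' @return site_index_table
#' @export
rarefied_richness <- function(cm, n, reps = 100, seed = 1) {
  assert_that(n >= 1 && reps >= 1, "n and reps must be >= 1")
  set.seed(seed)
  totals <- rowSums(cm$n_records)
  vals <- rep(NA_real_, length(cm$sites))
  for (i in seq_along(cm$sites)) {
    if (totals[i] < n) next
    pool <- rep.int(seq_along(cm$species), cm$n_records[i, ])
    if (totals[i] == n) { vals[i] <- length(unique(pool)); next }
    vals[i] <- mean(vapply(seq_len(reps), function(k)
      length(unique(sample(pool, n))), 0))
  }
  if (all(is.na(vals)))
    warning("n exceeds every site's record count; all values missing")
  site_index_table(cm, vals, "rarefied_richness",
                   list(n = n, reps = reps, seed = seed))
}

#' Weighted endemism per site
#'
#' WE(site) = sum over species present of 1 / (number of occupied sites),
#' so each species contributes its inverse range size and the WE values sum
#' to the species count over the whole study.
#'
#' @param cm community_matrix
#' @return site_index_table
#' @export
weighted_endemism <- function(cm) {
  range_size <- colSums(cm$incidence)
  w <- sweep(cm$incidence, 2L, range_size, "/")
  site_index_table(cm, as.numeric(rowSums(w)), "weighted_endemism")
}

# --- phylogenetic machinery -------------------------------------------------
# tip x edge incidence over an ape::phylo: entry 1 when the edge lies on the
# tip's path to the root. Site spanning subtrees are then unions of tip paths.
tip_edge_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  edge_above <- integer(max(tree$edge))  # edge index whose child is the node
  edge_above[child] <- seq_len(nrow(tree$edge))
  root <- setdiff(parent, child)[1]
  M <- matrix(0L, n_tip, nrow(tree$edge),
              dimnames = list(tree$tip.label, NULL))
  for (tip in seq_len(n_tip)) {
    node <- tip
    while (node != root) {
      e <- edge_above[node]
      M[tip, e] <- 1L
      node <- parent[e]
    }
  }
  M
}

check_species_in_tree <- function(cm, tree) {
  missing <- setdiff(cm$species, tree$tip.label)
  if (length(missing))
    stop2(paste0("species absent from tree: ", paste(missing, collapse = ", ")))
}

# site x edge incidence: does any of the site's species use this edge
site_edge_incidence <- function(cm, tree) {
  check_species_in_tree(cm, tree)
  M <- tip_edge_incidence(tree)[cm$species, , drop = FALSE]
  (cm$incidence %*% M > 0) * 1L
}

#' Faith's phylogenetic diversity per site (rooted)
#'
#' Total branch length of the minimal subtree connecting a site's species to
#' the root. Sites with no species are missing.
#'
#' @param cm community_matrix
#' @param tree rooted `phylo` with branch lengths; tips must cover the
#'   community species (extra tips allowed)
#' @return site_index_table
#' @export
faith_pd <- function(cm, tree) {
  S <- site_edge_incidence(cm, tree)
  vals <- as.numeric(S %*% tree$edge.length)
  vals[rowSums(cm$incidence) == 0L] <- NA_real_
  site_index_table(cm, vals, "faith_pd")
}

#' Phylogenetic endemism per site
#'
#' Each branch of a site's spanning subtree contributes its length divided by
#' the number of sites whose subtree contains that branch, so PE values sum
#' to the total length of branches occupied anywhere.
#'
#' @inheritParams faith_pd
#' @return site_index_table
#' @export
phylogenetic_endemism <- function(cm, tree) {
  S <- site_edge_incidence(cm, tree)
  branch_sites <- colSums(S)
  w <- ifelse(branch_sites > 0, tree$edge.length / pmax(branch_sites, 1), 0)
  vals <- as.numeric(S %*% w)
  vals[rowSums(cm$incidence) == 0L] <- NA_real_
  site_index_table(cm, vals, "phylogenetic_endemism")
}

# --- beta diversity ---------------------------------------------------------

beta_from_abc <- function(a, b, c) {
  if (a + b + c == 0) return(c(sorensen = NA, simpson = NA, nestedness = NA))
  sor <- (b + c) / (2 * a + b + c)
  sim <- if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c))
  c(sorensen = sor, simpson = sim, nestedness = sor - sim)
}

#' Pairwise beta-diversity partition of two species sets
#'
#' With a shared species, b and c unique to each site:
#' sorensen = (b+c)/(2a+b+c), simpson (turnover) = min(b,c)/(a+min(b,c)),
#' nestedness = sorensen - simpson.
#'
#' @param site_a,site_b character vectors of species labels (both non-empty)
#' @return named vector (sorensen, simpson, nestedness)
#' @export
beta_pairwise <- function(site_a, site_b) {
  if (length(site_a) == 0L || length(site_b) == 0L)
    stop2("beta diversity is undefined for an empty species set")
  a <- length(intersect(site_a, site_b))
  b <- length(setdiff(site_a, site_b))
  c <- length(setdiff(site_b, site_a))
  beta_from_abc(a, b, c)
}

new_dissimilarity <- function(m, ids, metric) {
  dimnames(m) <- list(ids, ids)
  structure(m, metric = metric, class = c("dissimilarity_matrix", "matrix"))
}

#' Beta-diversity dissimilarity matrices over a community
#'
#' Computes all unordered site pairs and returns the three components of the
#' Sorensen partition. The phylogenetic family replaces species counts a/b/c
#' by shared and unique branch lengths of the two sites' rooted spanning
#' subtrees (PhyloSor family), partitioned with the same formulas. Sites with
#' no species are excluded with a warning.
#'
#' @param cm community_matrix
#' @param family `"taxonomic"` or `"phylogenetic"`
#' @param tree required for the phylogenetic family
#' @return list of three `dissimilarity_matrix` objects: sorensen, simpson,
#'   nestedness (phylosor/phylosim/phylosne for the phylogenetic family)
#' @export
beta_matrix <- function(cm, family = c("taxonomic", "phylogenetic"),
                        tree = NULL) {
  family <- match.arg(family)
  occupied <- rowSums(cm$incidence) > 0L
  if (any(!occupied))
    warning(sprintf("%d empty site(s) excluded from beta matrices",
                    sum(!occupied)))
  sites <- cm$sites[occupied]
  assert_that(length(sites) >= 2L, "need at least 2 non-empty sites")
  if (family == "taxonomic") {
    X <- cm$incidence[occupied, , drop = FALSE]
    lens <- rep(1, ncol(X))
    metrics <- c("sorensen", "simpson", "nestedness")
  } else {
    assert_that(!is.null(tree), "phylogenetic family requires a tree")
    X <- site_edge_incidence(cm, tree)[occupied, , drop = FALSE]
    lens <- tree$edge.length
    metrics <- c("phylosor", "phylosim", "phylosne")
  }
  # shared branch/species "length" for all pairs at once
  Xw <- sweep(X, 2L, lens, "*")
  A <- Xw %*% t(X)                      # shared length between sites i,j
  tot <- as.numeric(X %*% lens)         # per-site total
  n <- length(sites)
  B <- matrix(tot, n, n) - A            # unique to i
  C <- t(B)                             # unique to j
  minBC <- pmin(B, C)
  sor <- (B + C) / (2 * A + B + C)
  sim <- minBC / (A + minBC)
  sim[A + minBC == 0] <- 0
  nes <- sor - sim
  diag(sor) <- 0; diag(sim) <- 0; diag(nes) <- 0
  list(new_dissimilarity(sor, sites, metrics[1]),
       new_dissimilarity(sim, sites, metrics[2]),
       new_dissimilarity(nes, sites, metrics[3])) |>
    stats::setNames(metrics)
}

#' Write a dissimilarity matrix as square CSV with site ids
#' @param d dissimilarity_matrix
#' @param path output path
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(site = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a site index table as CSV
#' @param tab site_index_table
#' @param path output path
#' @export
write_site_index <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
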