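test_that("richness counts species per site, zero for empty sites", {
  cm <- make_cm(rbind(c(1, 1, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(richness(cm)$value, c(2, 0, 3))
  expect_equal(richness(make_cm(diag(3)))$value, c(1, 1, 1))
})

test_that("rarefied richness matches closed-form and degenerate cases", {
  # 10 records all one species: any subsample has 1 species
  cm1 <- make_cm(matrix(1, 1, 1), n_records = matrix(10, 1, 1))
  expect_equal(rarefied_richness(cm1, n = 5, reps = 20)$value, 1.0)
  # exhaustive draw returns both species exactly
  cm2 <- make_cm(matrix(1, 1, 2), n_records = matrix(c(5, 5), 1))
  expect_equal(rarefied_richness(cm2, n = 10, reps = 5)$value, 2.0)
  # hypergeometric oracle: E[S] = 1 + (1 - C(9,2)/C(10,2)) = 1.2
  cm3 <- make_cm(matrix(1, 1, 2), n_records = matrix(c(9, 1), 1))
  reps <- 10000
  est <- rarefied_richness(cm3, n = 2, reps = reps, seed = 42)$value
  se <- sqrt(0.2 * 0.8 / reps)
  expect_lt(abs(est - 1.2), 3 * se)
  # sites below n are missing; all-missing warns
  cm4 <- make_cm(rbind(c(1, 1), c(1, 0)), n_records = rbind(c(3, 3), c(1, 0)))
  v <- rarefied_richness(cm4, n = 4, reps = 10)$value
  expect_equal(v, c(2, NA))
  expect_warning(rarefied_richness(cm4, n = 100, reps = 2), "all values missing")
  # n = site total reproduces plain richness exactly
  set.seed(2)
  nrec <- matrix(rpois(12, 3) + 1, 3, 4)
  cm5 <- make_cm((nrec > 0) * 1, n_records = nrec)
  for (i in 1:3) {
    sub <- make_cm(cm5$incidence[i, , drop = FALSE],
                   n_records = nrec[i, , drop = FALSE])
    expect_equal(rarefied_richness(sub, n = sum(nrec[i, ]), reps = 3)$value,
                 richness(sub)$value)
  }
})

test_that("weighted endemism sums inverse range sizes and conserves totals", {
  # sp1 in 1 site, sp2 in 4 sites
  inc <- rbind(c(1, 1), c(0, 1), c(0, 1), c(0, 1))
  we <- weighted_endemism(make_cm(inc))$value
  expect_equal(we[1], 1 + 0.25)
  expect_equal(sum(we), 2)  # = number of species
  # property: total WE = species count on random communities
  set.seed(5)
  for (k in 1:5) {
    inc <- matrix(rbinom(30, 1, 0.5), 5, 6)
    inc[, colSums(inc) == 0] <- 1
    expect_equal(sum(weighted_endemism(make_cm(inc))$value), 6)
  }
})

test_that("Faith PD (rooted) matches hand-computed spanning subtrees", {
  tree <- ref_tree()  # ((A:1,B:1):1,C:2);
  cm <- make_cm(rbind(AB = c(1, 1, 0), ABC = c(1, 1, 1), C = c(0, 0, 1)))
  colnames(cm$incidence) <- colnames(cm$n_records) <- c("A", "B", "C")
  cm$species <- c("A", "B", "C")
  pd <- faith_pd(cm, tree)$value
  expect_equal(pd, c(3, 5, 2))
  expect_error(faith_pd(make_cm(matrix(1, 1, 1,
    dimnames = list(1, "missing_sp"))), tree), "absent from tree")
})

test_that("phylogenetic endemism divides branches by their site range", {
  tree <- ref_tree()
  # single-site community: PE = PD
  cm1 <- make_cm(matrix(c(1, 1, 0), 1, 3, dimnames = list(1, c("A", "B", "C"))))
  expect_equal(phylogenetic_endemism(cm1, tree)$value,
               faith_pd(cm1, tree)$value)
  # two sites sharing the A+B clade: shared branches halved
  cm2 <- make_cm(rbind(c(1, 0, 0), c(0, 1, 0)))
  colnames(cm2$incidence) <- colnames(cm2$n_records) <- c("A", "B", "C")
  cm2$species <- c("A", "B", "C")
  pe <- phylogenetic_endemism(cm2, tree)$value
  # each site: pendant 1 (alone) + internal 1 shared by 2 -> 1 + 0.5
  expect_equal(pe, c(1.5, 1.5))
  # PE total = occupied branch length (= PD of the pooled assemblage)
  pooled <- make_cm(matrix(pmin(colSums(cm2$incidence), 1), 1, 3,
                           dimnames = list(1, c("A", "B", "C"))))
  expect_equal(sum(pe), faith_pd(pooled, tree)$value)
})

test_that("beta_pairwise matches the worked partition examples", {
  b <- beta_pairwise(c("s1", "s2", "s3"), c("s2", "s3", "s4", "s5"))
  expect_equal(unname(b), c(3 / 7, 1 / 3, 2 / 21), tolerance = 1e-15)
  expect_equal(unname(beta_pairwise(c("a", "b"), c("a", "b"))), c(0, 0, 0))
  expect_equal(unname(beta_pairwise(c("a"), c("b"))), c(1, 1, 0))
  expect_error(beta_pairwise(character(0), "a"), "empty species set")
})

test_that("beta_matrix agrees with beta_pairwise and partitions additively", {
  set.seed(9)
  inc <- matrix(rbinom(40, 1, 0.5), 5, 8)
  inc[rowSums(inc) == 0, 1] <- 1
  inc[, colSums(inc) == 0] <- 1
  cm <- make_cm(inc)
  b <- beta_matrix(cm)
  for (i in 1:4) for (j in (i + 1):5) {
    ref <- beta_pairwise(cm$species[inc[i, ] == 1], cm$species[inc[j, ] == 1])
    expect_equal(b$sorensen[i, j], unname(ref["sorensen"]), tolerance = 1e-12)
    expect_equal(b$simpson[i, j], unname(ref["simpson"]), tolerance = 1e-12)
  }
  expect_equal(max(abs(b$sorensen - b$simpson - b$nestedness)), 0,
               tolerance = 1e-12)
  expect_true(isSymmetric(unclass(b$sorensen)))
  expect_true(all(diag(b$sorensen) == 0))
})

test_that("adding a shared species never increases sorensen", {
  set.seed(10)
  for (k in 1:20) {
    a <- sample(letters, sample(3:8, 1))
    b <- sample(letters, sample(3:8, 1))
    new_sp <- "ZZ"
    s0 <- beta_pairwise(a, b)["sorensen"]
    s1 <- beta_pairwise(c(a, new_sp), c(b, new_sp))["sorensen"]
    expect_lte(s1, s0 + 1e-12)
  }
})

test_that("phylogenetic beta matches hand enumeration and reduces on star trees", {
  tree <- ref_tree()
  # sites {A} and {B}: shared root-path branch length 1, unique pendants 1,1
  cm <- make_cm(rbind(c(1, 0, 0), c(0, 1, 0)))
  colnames(cm$incidence) <- colnames(cm$n_records) <- c("A", "B", "C")
  cm$species <- c("A", "B", "C")
  pb <- beta_matrix(cm, family = "phylogenetic", tree = tree)
  expect_equal(pb$phylosor[1, 2], 0.5)
  # identical sites -> 0
  cm_same <- make_cm(rbind(c(1, 1, 0), c(1, 1, 0)))
  colnames(cm_same$incidence) <- colnames(cm_same$n_records) <- c("A", "B", "C")
  cm_same$species <- c("A", "B", "C")
  expect_equal(beta_matrix(cm_same, family = "phylogenetic",
                           tree = tree)$phylosor[1, 2], 0)
  # partition additivity holds for the phylo family too
  expect_equal(max(abs(pb$phylosor - pb$phylosim - pb$phylosne)), 0,
               tolerance = 1e-12)
  # star tree with unit lengths reduces to the taxonomic partition
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(11)
  inc <- matrix(rbinom(20, 1, 0.6), 4, 5,
                dimnames = list(1:4, c("A", "B", "C", "D", "E")))
  inc[rowSums(inc) == 0, 1] <- 1
  inc[, colSums(inc) == 0] <- 1
  cm2 <- make_cm(inc)
  tax <- beta_matrix(cm2)
  phy <- beta_matrix(cm2, family = "phylogenetic", tree = star)
  expect_equal(unclass(phy$phylosor), unclass(tax$sorensen),
               ignore_attr = TRUE, tolerance = 1e-12)
  # empty site excluded with warning
  inc3 <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 0, 0, 0), c(0, 1, 1, 0, 0))
  colnames(inc3) <- c("A", "B", "C", "D", "E")
  expect_warning(b3 <- beta_matrix(make_cm(inc3)), "empty site")
  expect_equal(nrow(b3$sorensen), 2L)
})
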