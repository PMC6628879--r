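# Synthetic landscape generator: a stated world of n_regions contiguous biotas
# planted side by side, each with its own endemic species and clade, used to
# exercise every downstream analysis without external data. Endemics of one
# region are congruent: their range centers jitter around the region's block
# center, so the region hosts a shared biota (and, at small range_radius, a
# congruent cluster in the areas-of-endemism sense).

#' Configuration for the synthetic landscape generator
#'
#' The landscape is a row of `n_regions` square blocks of side `block_size`
#' (planar units). Each region receives `n_species_per_region` endemic
#' species whose occurrence points are drawn uniformly inside a disk of
#' radius `range_radius` around a region-interior center; `n_shared_species`
#' widespread species span the whole landscape. Environmental bands are
#' smooth coordinate gradients plus Gaussian noise, and the phylogeny groups
#' each region's endemics into a clade (unit branch lengths).
#'
#' @param n_regions number of planted biotas (>= 1)
#' @param n_species_per_region endemics per region (>= 1)
#' @param n_shared_species widespread species across regions (>= 0)
#' @param range_radius spatial spread of an endemic species, in map units;
#'   the default (0.3 * block_size) makes endemics span a good fraction of
#'   their region, as regional endemics do
#' @param n_points_per_species records per species (>= 1)
#' @param env_gradients number of environmental predictor bands (>= 1)
#' @param noise_sd white-noise standard deviation added to each band
#' @param seed integer seed fixing all randomness
#' @param block_size side of one region block (map units)
#' @param center_jitter half-width of the uniform jitter of species range
#'   centers around their region's block center; small values give highly
#'   congruent ranges
#' @param env_cellsize cell size of the environmental rasters
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(n_regions = 3, n_species_per_region = 5,
                             n_shared_species = 0,
                             range_radius = 0.4 * block_size,
                             n_points_per_species = 20, env_gradients = 2,
                             noise_sd = 0, seed = 1, block_size = 10,
                             center_jitter = min(range_radius / 4,
                                                 block_size / 2 - range_radius),
                             env_cellsize = block_size / 20) {
  assert_that(n_regions >= 1 && n_species_per_region >= 1 &&
                n_points_per_species >= 1 && env_gradients >= 1,
              "all counts must be >= 1")
  assert_that(n_shared_species >= 0, "n_shared_species must be >= 0")
  assert_that(range_radius > 0, "range_radius must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  if (range_radius > block_size / 2)
    stop2("region blocks too small for range_radius (need range_radius <= block_size/2)")
  assert_that(center_jitter >= 0 &&
                center_jitter + range_radius <= block_size / 2 + 1e-9,
              "center_jitter + range_radius must fit inside the block")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic landscape
#'
#' @param config a [synthetic_config()]
#' @return list of class `synthetic_landscape` with elements `occ`
#'   (occurrence_table), `tree` (phylo), `env` (raster_stack), `area`
#'   (study_area), and `truth` (planted region of every species, the species
#'   range centers/radius, and a region-label raster aligned with `env`)
#' @export
generate_synthetic_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  B <- config$block_size
  R <- config$n_regions
  width <- R * B
  area <- study_area_rect(0, 0, width, B)

  jit <- config$center_jitter
  species <- character(0); region_of <- integer(0)
  centers <- NULL
  sp_all <- character(0); x_all <- numeric(0); y_all <- numeric(0)
  for (r in seq_len(R)) {
    bcx <- (r - 0.5) * B; bcy <- B / 2
    for (j in seq_len(config$n_species_per_region)) {
      nm <- sprintf("r%d_sp%02d", r, j)
      cx <- bcx + stats::runif(1, -jit, jit)
      cy <- bcy + stats::runif(1, -jit, jit)
      th <- stats::runif(config$n_points_per_species, 0, 2 * pi)
      rad <- config$range_radius * sqrt(stats::runif(config$n_points_per_species))
      sp_all <- c(sp_all, rep(nm, config$n_points_per_species))
      x_all <- c(x_all, cx + rad * cos(th))
      y_all <- c(y_all, cy + rad * sin(th))
      species <- c(species, nm); region_of <- c(region_of, r)
      centers <- rbind(centers, c(cx, cy))
    }
  }
  if (config$n_shared_species > 0) {
    for (j in seq_len(config$n_shared_species)) {
      nm <- sprintf("shared_sp%02d", j)
      sp_all <- c(sp_all, rep(nm, config$n_points_per_species))
      x_all <- c(x_all, stats::runif(config$n_points_per_species, 0, width))
      y_all <- c(y_all, stats::runif(config$n_points_per_species, 0, B))
      species <- c(species, nm); region_of <- c(region_of, NA_integer_)
      centers <- rbind(centers, c(NA, NA))
    }
  }
  occ <- occurrence_table(sp_all, x_all, y_all)

  # phylogeny: one clade (polytomy, unit lengths) per region; shared species
  # attach at the root
  clades <- vapply(seq_len(R), function(r) {
    tips <- species[region_of == r & !is.na(region_of)]
    paste0("(", paste0(tips, ":1", collapse = ","), "):1")
  }, "")
  shared <- species[is.na(region_of)]
  parts <- c(clades, if (length(shared)) paste0(shared, ":2"))
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))

  # environmental bands: smooth gradients aligned with the region axis
  tmpl <- raster_template(0, 0, width, B, config$env_cellsize)
  cc <- cell_centers(tmpl)
  nc_cells <- nrow(cc)
  bands <- list()
  for (g in seq_len(config$env_gradients)) {
    base <- switch(((g - 1) %% 3) + 1,
                   cc[, 1] / width,
                   cc[, 2] / B,
                   sin(pi * cc[, 1] / width) * cc[, 2] / B)
    v <- base + if (config$noise_sd > 0)
      stats::rnorm(nc_cells, 0, config$noise_sd) else 0
    bands[[paste0("env", g)]] <- set_values_rowmajor(tmpl, v)
  }
  env <- raster_stack(bands)

  region_raster <- set_values_rowmajor(tmpl, pmin(floor(cc[, 1] / B) + 1, R))

  truth <- list(
    region_of_species = stats::setNames(region_of, species),
    centers = stats::setNames(
      data.frame(sp = species, cx = centers[, 1], cy = centers[, 2]), c("sp", "cx", "cy")),
    range_radius = config$range_radius,
    region_raster = region_raster
  )
  structure(list(occ = occ, tree = tree, env = env, area = area,
                 truth = truth, config = config),
            class = "synthetic_landscape")
}
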