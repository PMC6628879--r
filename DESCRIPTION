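Package: divscape
Title: Mapping Spatial Patterns of Biodiversity, Endemism and Bioregions
Version: 0.1.0
Authors@R: person("divscape", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping spatial patterns of biodiversity from point
    occurrences, phylogenies and environmental rasters: diversity and
    endemism indices (species richness, rarefied richness, weighted and
    phylogenetic endemism, Faith PD) on equal-area hexagon grids;
    Sorensen/Simpson beta-diversity partition into turnover and nestedness,
    with phylogenetic (PhyloSor) analogues; ordination-based
    bioregionalization (NMDS composition interpolation with spatial
    autocorrelation premise test, RGB composites and unsupervised
    classification); kernel-based delimitation of areas of endemism across
    multiple scales with consensus surfaces; spatial interpolators (nearest
    neighbour, thin-plate spline, ordinary kriging) and GLM predictive
    surfaces; species distribution model pre/post-processing (Bioclim
    envelope, pseudo-absences, AUC/Kappa/TSS validation, niche overlap);
    and raster-stack statistics (correlation, variable clustering, PCA cube
    with scenario projection, Moran's I, variograms). Rasters are plain-text
    ESRI ASCII grids; vector masks are GeoJSON; trees are newick.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
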