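---
title: "Methods and design notes for divscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for divscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

divscape maps spatial patterns of biodiversity from three standardized
inputs: point occurrences (`sp, x, y` tables), a polygon mask of the study
area, and optional phylogenies and environmental raster stacks. This
vignette documents the models implemented, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic-data generator does and does not establish.

## Coordinate model and file formats

All geometry is planar. Inputs in geographic degrees are accepted but
flagged once: distances are then degree-space distances, and users who need
metric behaviour should supply coordinates in an equal-area projection.
This keeps every distance-based method (hexagon tiling, kernels,
variograms, kriging) defined by a single Euclidean metric.

Raster I/O uses the ESRI ASCII grid format (plain text, square cells,
`NODATA_value` sentinel) rather than GeoTIFF: no GeoTIFF-capable R package
is available in the supported dependency set, and the in-memory contract
(dimensions, affine placement, nodata, band alignment) is unchanged by the
container format. Vector masks are GeoJSON (Polygon / MultiPolygon, holes
supported, unclosed rings auto-closed with a warning); trees are newick
parsed with **ape**.

## Hexagonal sample units

Sample units are flat-topped equal-area hexagons of user-chosen side *s*
(area $\tfrac{3\sqrt3}{2}s^2$), anchored at the lower-left corner of the
mask bounding box. Orientation and anchor are conventions, not science: any
fixed choice gives a translation-consistent community matrix, which the
tests verify. "Side" means edge length, not apothem. Cells are retained
when they intersect the mask at all, so coastal records are not lost; a
record is assigned to the unique hexagon containing it (nearest-center
assignment, which is exact for a hexagonal tiling; ties on shared edges go
to the smaller cell id). Records outside every retained cell are dropped
and counted. Empty cells stay in the community matrix: richness there is 0,
while indices whose preconditions fail report missing values, never silent
zeros.

## Diversity and endemism indices

* **Richness**: species count per site. **Rarefied richness**: mean species
  count over repeated uniform without-replacement draws of *n* records from
  the site's record pool; sites with fewer than *n* records are missing.
  Drawing records (not species) reflects how sampling effort actually
  operates; the hypergeometric closed form for two species is used as the
  test oracle.
* **Weighted endemism**: $WE(i)=\sum_{j \in i} 1/\mathrm{range}_j$ with
  range = number of occupied sites, so WE sums to the species count — a
  conservation identity the tests assert.
* **Faith PD** is *rooted*: the path to the root belongs to every site's
  spanning subtree. This makes single-tip PD nonzero and gives the clean
  identity PE = PD for a site that is sole occupant of its branches.
* **Phylogenetic endemism** divides each branch of the site's spanning
  subtree by the number of sites whose subtree contains it; PE totals the
  occupied branch length.
* **Beta diversity** uses the Sørensen partition: with shared/unique
  species counts $a, b, c$, dissimilarity $(b+c)/(2a+b+c)$ splits into
  turnover $\min(b,c)/(a+\min(b,c))$ (the Simpson component) and a
  nestedness remainder. The phylogenetic family substitutes shared and
  unique branch lengths of the two rooted spanning subtrees (PhyloSor) into
  the same formulas, so on a star tree with unit branch lengths it reduces
  exactly to the taxonomic partition. The index family is a documented
  design decision: the partition into turnover and nestedness components
  is specified by the method lineage, the formulas by the Sørensen/Simpson
  tradition. Empty sites are excluded from beta matrices with a warning.

## Composition interpolation (SCI/PCI)

The pipeline is: community matrix → beta dissimilarity matrix → NMDS →
spatial-autocorrelation premise test → per-axis interpolation to rasters →
optional RGB composite and unsupervised classification into bioregions.
The phylogenetic variant is the same code path fed the phylogenetic beta
matrix.

NMDS minimizes Kruskal stress-1 with monotone regression (via
`vegan::monoMDS`), best of `n_restarts` starts — a metric-scaling start
plus seeded random configurations; scores are column-centered, and
identical seeds give identical scores. Stress is rank-based, hence
invariant under monotone transforms of the dissimilarities (tested within
restart tolerance).

Spatial structure in the scores is a premise of interpolating them.
Moran's I is computed per axis with inverse-distance, row-standardized
weights between hexagon centers (zero self-weight) — the weights scheme is
a design choice, as none is prescribed — with a two-sided permutation
p-value. A violated premise (p > 0.05 on any axis) warns and proceeds by
default; `strict_premise = TRUE` aborts instead. The null expectation
$-1/(n-1)$ and the empirical type-I error of the permutation test are both
asserted in the acceptance suite.

The RGB composite rescales the first three axis rasters to 0–255 by
per-band min–max with the floor convention (the 2%–98% percentile option is
deliberately off by default). Classification z-scores the bands and runs
either k-means (best of `n_init` starts) or CLARA-style k-medoids (PAM on a
subsample of cells, all cells assigned to the nearest medoid).
Random-forest proximity clustering is out of scope.

## Areas of endemism by kernel interpolation

Each species is summarized by its centroid and maximum centroid-to-record
distance $r_s$. At scale $R$, species with $r_s \le R$ contribute a quartic
(biweight) kernel $K(u) = (1-u^2)^2$, $u = d/R$, centered on the centroid
with weight $w_s = 1 - r_s/R$, so the most range-restricted species count
most; wider-ranging species are excluded at that scale and listed. The
consensus across scales is the cell-wise mean of per-scale surfaces, each
rescaled to [0, 1] by its own maximum (all-zero surfaces skipped with a
warning). Areas of endemism are 8-connected components of cells at or above
a threshold fraction (default 0.5) of the surface maximum; a species
belongs to a component when its kernel disk reaches it, and components with
fewer than two species are discarded — endemism requires congruence.
Default scales are a geometric series of five radii between the 10th and
90th percentiles of the positive range radii. The kernel form, weighting
and extraction rules are design commitments documented here: the method is
described functionally in its source literature and the original algorithm
was not available for reconciliation, so a fully specified, testable
surface was chosen over an unimplementable citation.

## Interpolators and predictive surfaces

* **Nearest neighbour**: ties go to the smallest sample index.
* **Thin-plate spline**: $r^2\log r$ basis plus an affine part;
  $\lambda=0$ interpolates exactly and reproduces affine surfaces;
  $\lambda \to \infty$ tends to the least-squares plane. Collinear samples
  make the exact problem singular and raise an error suggesting smoothing.
* **Ordinary kriging**: empirical semivariogram
  $\gamma(h)=\mathrm{mean}\,\tfrac12(z_i-z_j)^2$ per lag bin; weighted
  least-squares fit (weights = pair counts) over exponential, spherical and
  gaussian models, best model by weighted residual. The kriging system uses
  $\gamma(0)=0$ on the diagonal so zero-nugget kriging is exact at data
  points. A tiny numerical nugget (10⁻³ of the sill for the gaussian model,
  10⁻¹⁰ otherwise) stabilizes the notoriously ill-conditioned gaussian
  system; because it is applied consistently to the matrix and the
  right-hand side, exactness at data points is unaffected. Neighbourhood is
  global up to 2000 samples, then the 64 nearest. Duplicate locations are
  merged to their mean with a warning.
* **GLM surfaces**: canonical-link gaussian/poisson/binomial fits of a
  sampled variable on raster predictors; the single quality number reported
  is percent deviance explained. Rank-deficient designs error naming the
  collinear bands.
* **Sampling effort**: quartic kernel density of all records, normalized so
  cell area × total density equals the record count (up to edge
  truncation).

Diversity surfaces (richness/endemism/PD maps) are compositions: index per
hexagon → sample set at hexagon centers → any interpolator; the predictive
variants feed the same sample set to the GLM machinery.

## SDM tools

The **Bioclim** envelope scores each cell per band by the percentile rank
*p* of its value within the presence sample (midpoint tie convention),
band score $2\min(p, 1-p)$, aggregated by the minimum across bands; values
outside the presence min–max score 0. This is the classic definition,
adopted because the source names the method without formulas. Pseudo-
absences come uniform over the study area or weighted by the sampling-
effort density of the whole species group (cells within `min_dist` of a
focal presence — and the presence cells themselves — are ineligible);
`min_dist` defaults to 0. Validation statistics follow the standard
confusion-matrix formulas with Cohen's kappa from marginal expectations;
undefined ratios are missing, never 0. AUC is the Mann–Whitney statistic
with half-credit for ties, verified against brute-force pair enumeration.
Niche overlap reports Schoener's D and Hellinger-based I on rasters
normalized to sum 1 over shared valid cells.

## Raster-stack statistics

PCA standardizes bands by default (correlation PCA): the motivating use
case mixes units across climate variables, and the equal-share significance
rule — retain components whose share of variance strictly exceeds
$100/p\%$ for *p* input bands, e.g. 5.26% for 19 — presumes comparable
per-variable shares. Covariance PCA sits behind `standardize = FALSE`.
Component signs are fixed (largest-magnitude loading positive) for
reproducibility, and scenario projection applies the training means, scales
and loadings unchanged. Variable clustering is deliberately simple:
connected components of the graph with edges $|r| \ge t$ — a documented
divergence from more elaborate clustering-of-variables algorithms that
honours the same contract (high correlation within groups). Global Moran's
I on rasters uses binary rook/queen contiguity with permutation inference;
the raster variogram subsamples cells (seeded) beyond a pair budget.

## The synthetic landscape

The generator plants `n_regions` square blocks in a row, each with its own
biota: `n_species_per_region` endemic species whose range centers jitter
uniformly (half-width `center_jitter`) around the block center and whose
records fall uniformly in a disk of radius `range_radius`; shared species
span the whole landscape. Environmental bands are smooth coordinate
gradients plus white noise, the phylogeny groups each region's endemics in
a clade (unit branch lengths), and a truth object records every planted
assignment. Defaults — blocks of side 10, range radius 0.4 × block, jitter
radius/4, 20 points per species — were chosen once so that regional
endemics overlap strongly within their region (a biota, and at small radii
a congruent cluster) while staying strictly inside their block; a
configuration is rejected when the range disk cannot fit the block.

What the generator does *not* emulate: sampling bias, range boundaries
shaped by environment, spatial aggregation of records within ranges,
imperfect detection, taxonomic noise. A green end-to-end test therefore
establishes that the pipeline recovers planted structure under clean
conditions — not that it is robust to the messiness of real occurrence
data.

## Numerical conventions and limitations

* Missing always propagates as NA; no statistic silently becomes 0.
* Assignment ties (hexagon edges, nearest-neighbour midpoints) resolve to
  the smaller index, a convention the documentation states wherever it
  applies.
* All randomness flows through explicit integer seeds; restarts derive
  child seeds deterministically.
* Polygon validity checking is limited to ring closure and degenerate-ring
  detection; self-intersecting rings are not repaired.
* Hexagon/mask intersection is probed on a finite point set (center,
  vertices, edge midpoints, mask vertices), which can in principle miss a
  sliver intersection thinner than the probe spacing.
* Planar geometry on degree coordinates distorts distances at high
  latitude; supply projected coordinates when that matters.
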