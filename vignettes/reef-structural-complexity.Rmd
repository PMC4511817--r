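---
title: "Quantifying reef structural complexity from DEMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reef structural complexity from DEMs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reeftopo)
```

## The measurement problem

A photogrammetric survey of a reef plot yields a digital elevation model
(DEM) — a regular grid of elevations in metres on a local planar coordinate
system — and an orthophoto from which every living coral colony and abiotic
patch (rock/rubble, sand) is digitized as a labelled polygon. `reeftopo`
quantifies, per cell, per colony and per benthic class, the structural
properties that matter ecologically: slope, curvature, 3D/2D surface area
("surface complexity"), linear rugosity, and percent cover, and then tests
whether the classes differ.

Everything downstream fixes three conventions, recorded in every
`metric_raster` and in run logs:

* **Coordinates** are local planar metres. Cell `(r, c)` of a grid with
  top-left outer corner `origin` has its centre at
  `origin + ((c - 0.5) L, -(r - 0.5) L)`; rows run north to south. Any CRS
  tag in input files is ignored — reef plots are surveyed in tape-and-depth
  local frames, and reprojection is out of scope.
* **Elevation is up-positive.** Depth-gauge products store down-positive
  values; `load_dem(depth_mode = TRUE)` negates on load so slope and
  curvature signs are unambiguous. The negation is an involution, so a
  depth-mode round trip restores the input.
* **Square cells are mandatory** because every 3 × 3 operator below assumes
  a single cell size `L`.

## Terrain derivatives

**Slope** uses the average-maximum technique: the gradient of the plane
fitted to the 3 × 3 window with Horn's weighted third-order differences,

```
dz/dx = ((Z3 + 2 Z6 + Z9) - (Z1 + 2 Z4 + Z7)) / (8L)
dz/dy = ((Z1 + 2 Z2 + Z3) - (Z7 + 2 Z8 + Z9)) / (8L)
```

with the window elevations `Z1..Z9` numbered row-wise from the top-left.
Percent slope is `tan θ × 100`. This realization was chosen because it is
the standard GIS meaning of "average maximum" and is exact on planes — the
property the test suite exploits.

**Curvature** comes from the Zevenbergen–Thorne partial-quartic fit through
the cell and its eight neighbours (`fit_quadratic_window()`), whose
second-order coefficients `D, E, F` and gradients `G, H` give three
measures, each multiplied by −100 so that *positive combined curvature
means convex*:

* combined `= −2(D + E) × 100`
* profile `= 2(DG² + EH² + FGH)/(G² + H²) × 100` (parallel to the
  maximum-slope direction; negative on convex forms)
* planform `= −2(DH² + EG² − FGH)/(G² + H²) × 100` (perpendicular;
  positive on convex forms)

A dome therefore scores positive combined, negative profile and positive
planform curvature, and a bowl the exact negation — the package's tests
assert this antisymmetry. On level cells (`G = H = 0`) the directional
curvatures are defined as 0 rather than missing, so flat sand does not
propagate `NA` through class summaries. The fit reproduces any quadratic
surface exactly, which provides machine-precision oracles.

Units are 1/100 of the z-unit per map unit. `z_unit_scale` (default 1)
rescales the outputs to another reference z-unit; it is never applied
implicitly, because silent unit conversion is the classic source of
incomparable curvature numbers between studies. Since published work is
inconsistent about the cell size appropriate for colony-scale curvature,
cell size is a free input here; 0.5-cm cells resolve individual colony
morphology at survey scale.

**Border policy:** the one-cell border and any window touching nodata are
masked. Reflection padding would fabricate data at exactly the places
(colony edges) where the metrics matter.

## Surface complexity

For each annotated feature, the DEM restricted to cells whose *centres*
fall inside the polygon is draped: each cell splits into two triangles
along the fixed top-left → bottom-right diagonal, on corner elevations
interpolated as the mean of the (up to four) adjacent cell centres. The
reported ratio uses the rasterised planimetric area `n_cells · L²` as the
denominator so numerator and denominator describe the same cell set; the
exact vector polygon area is reported alongside so rasterisation error is
auditable. Cell-centre membership (even-odd rule with a half-open tie
direction) was chosen over partial-cell weighting because it makes the
annotation layer a true partition — every cell belongs to at most one
colony — which the zonal stage requires.

Two consequences are worth noting. First, the drape is 2.5D: true
overhangs (plating *Acropora* canopies) cannot be represented, so the
computed area is that of the drape surface — a known lower bound. Second,
corners on the outer grid boundary interpolate fewer than four cells, so a
feature touching the grid edge is measured slightly flatter; validation
polygons are inset by one cell when exactness matters.

## Rugosity

`extract_profile()` samples a straight transect at the largest uniform
spacing not exceeding `step` (default one cell) that divides the transect
length evenly — both endpoints are stations, and the trace is invariant to
direction reversal. Elevations are bilinear in the cell-centre lattice;
points in the outer half-cell ring clamp onto the lattice hull. The
rugosity index is path length over chainage, ≥ 1 with equality only on a
level trace.

Straight transects with bilinear sampling were preferred over cell-to-cell
path tracing on a cost surface because grid paths inflate diagonal
distances by construction, whereas straight-line traces are analytically
checkable (a unit-slope triangular wave gives exactly √2; a sinusoid
matches its arc-length quadrature). The default plan — long-axis transects
at 1/3 and 2/3 of the width, short-axis at 1/3 and 2/3 of the length, and
both diagonals — covers horizontal, vertical and diagonal directions with
six reproducible placements, expressed in fractional coordinates of the
cell-centre lattice and overridable in configuration.

## Zonal statistics and cover

`rasterize_partition()` labels each cell by cell-centre membership with the
same tie rule as the drape, and refuses overlapping polygons outright
(naming both features and the cell) rather than resolving them silently.
Per-feature summaries are mean ± SE (`sd/√n`, n−1 denominator) over
unmasked cells; a feature with fewer than two contributing cells reports a
*missing* SE, never 0.

Class-level statistics follow two different replication models, matching
how such data are analysed in practice: surface complexity and slope are
summarised over features (the colony is the biological replicate), while
curvature is pooled over cells within the class. The pooled mean and SE are
reconstructed exactly from the per-feature `(mean, SE, n)` triples, so no
cell-level data needs to be carried around. Percent cover uses vector
polygon areas clipped to the plot extent — not rasterised areas — because
digitised cover should not depend on DEM resolution; over an exhaustive
partition the covers sum to 100 within rounding.

## Statistics

The comparison stage mirrors standard community-ecology practice: an
initial two-response MANOVA (surface complexity, percent slope), then
univariate one-way ANOVAs with Tukey's HSD at α = 0.01.

* The log-transform rule had to be made explicit: data are log-transformed
  when the pooled within-group residual skewness exceeds 1 in absolute
  value (or when forced per metric in configuration), and the decision is
  recorded on the sample. A fixed threshold makes the screen deterministic
  and auditable.
* ANOVA is the classical decomposition (delegated to `stats::lm`); Tukey's
  HSD uses the Tukey–Kramer studentized-range statistic with p-values from
  `stats::ptukey`, cross-checked against `stats::TukeyHSD`.
* The MANOVA statistic is Wilks' Λ with Rao's F approximation — the most
  common default where the choice is not dictated. It is computed directly
  from the within/between cross-product matrices (and cross-checked against
  `stats::manova`) so that a single-response call reduces *exactly* to the
  univariate F, a reduction the test suite asserts.

## What the synthetic generator does and does not emulate

`make_colony_field()` emulates the geometry of a surveyed plot — by default
25 × 6 m at 0.5-cm cells — with non-overlapping colonies of four
morphotypes on a gently undulating matrix (2 mm amplitude, 4 m wavelength:
visible to rugosity, negligible to colony truth values):

| morphotype | shape | default (radius, height) | closed-form complexity |
|---|---|---|---|
| mounding | spherical cap | 0.30 m, 0.15 m | `(a² + h²)/a²` = 1.25 |
| plating | raised disc, linear rim (0.12 m) | 0.30 m, 0.30 m | `((a−w)² + (2a−w)√(w²+h²))/a²` ≈ 2.08 |
| encrusting | low cosine mound | 0.25 m, 0.04 m | — |
| branching | high-frequency ridge field (λ = 0.06 m) | 0.25 m, 0.10 m | — |

Footprints are circles (96-gon) placed by seeded rejection sampling with a
fixed attempt cap; identical `(seed, parameters)` regenerate the scene
bit-for-bit. The shape parameters were chosen once so that (i) each
closed-form colony is resolved by ≥ 20 cells per radius even at the coarser
1-cm and 0.75-cm cells used in validation, keeping drape recovery inside
2%, and (ii) the class ordering plating/branching > mounding/encrusting >
matrix — the qualitative fingerprint of complex reef communities — holds.

What passing these tests shows: the geometric operators recover known
areas, slopes and curvatures through the full I/O → terrain → zonal chain.
What they do not show: behaviour on real photogrammetric data with
reconstruction noise, holes, overhangs, ragged colony outlines, or
mis-digitised annotations. The generator has no orthophoto texture, no
reconstruction error model, and its colonies are radially symmetric.

## Validation problem sizes

The test suite and the acceptance script run at deliberately modest sizes:
analytic grids of 10²–10⁴ cells; a hemisphere at 100 cells per radius
(complexity within 5% of 2 — the rim is genuinely resolution-limited); a
colony field of 7 × 4 m at 0.75-cm cells (≈ 0.5 M cells, eight colonies,
two matrix patches); and a 2,000-replicate type-I calibration of the ANOVA
(8 groups, n = 30), whose rejection rate at α = 0.01 must land within
±0.6 points of 1%. These sizes were chosen as the smallest at which each
property is cleanly observable; all generators scale to full survey
dimensions.

## Known limitations

* The GeoTIFF codec is deliberately minimal: single-band, uncompressed,
  strip-organised files with `ModelPixelScale`/`ModelTiepoint`
  georeferencing and the GDAL nodata tag. Tiled, compressed or multi-band
  rasters are rejected with explicit messages rather than half-read.
* 2.5D throughout: overhanging morphology is projected onto the drape.
* Boundary cells of a feature are all-or-nothing (cell-centre rule);
  features smaller than a cell are flagged, not measured.
* Curvature class means pool cells, so colonies contribute in proportion
  to their area — feature-weighted curvature summaries are available by
  treating the per-feature means as replicates, and the two choices differ
  on strongly size-heterogeneous communities.
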