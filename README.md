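# reeftopo

Quantifying 3D structural complexity of coral reefs from digital elevation
models.

The structural complexity of a reef — its rugosity, slope, curvature, and
surface area per unit of planimetric area — is a primary driver of the
biodiversity and productivity of the benthic community, yet most survey
methods reduce the habitat to two dimensions. Photogrammetric
(Structure-from-Motion) surveys now produce sub-centimetre digital
elevation models (DEMs) and orthophotos of reef plots; `reeftopo` turns
those products, together with polygon annotations of every coral colony and
substrate patch, into per-colony and per-class structural metrics and the
statistics to compare them.

For a DEM `z(x, y)` on square cells of size `L` the package computes:

- **Percent slope** by the average-maximum technique on each 3 × 3 window
  (Horn's weighted differences): `tan θ = √((∂z/∂x)² + (∂z/∂y)²)`,
  reported as `tan θ × 100` (a 45° plane is 100%).
- **Curvature** from the Zevenbergen–Thorne nine-cell quadratic fit, scaled
  by −100 so convex (dome-like) forms have positive combined curvature:
  combined `−2(D + E)·100`, profile (parallel to maximum slope)
  `2(DG² + EH² + FGH)/(G² + H²)·100`, planform (perpendicular)
  `−2(DH² + EG² − FGH)/(G² + H²)·100`.
- **Surface complexity** of each annotated feature: the ratio of draped 3D
  surface area (two triangles per cell on corner-interpolated elevations)
  to planimetric 2D area, always ≥ 1.
- **Linear rugosity** along straight transects: path distance
  `Σ√(Δc² + Δz²)` over the straight-line distance, averaged over a
  six-transect plan (two long-axis, two short-axis, two diagonals).
- **Percent cover** per benthic class from vector polygon areas, and zonal
  class summaries (the colony is the replicate for surface complexity and
  slope; curvature statistics pool cells within a class).
- **Group comparisons**: a skewness-screened log transform, one-way ANOVA,
  Tukey's HSD at α = 0.01, and a two-response MANOVA via Wilks' Λ with
  Rao's F approximation.

A synthetic-reef generator (`make_analytic_surface()`,
`make_colony_field()`, `make_grouped_metrics()`) builds scenes with
closed-form ground truth — planes, domes, spherical-cap and plated-disc
colonies on an undulating matrix — so the whole pipeline can be validated
without survey data.

## Worked example

Simulate a 7 × 4 m plot (1-cm cells) with two colonies each of four
morphotypes, and run the per-feature pipeline:

```r
library(reeftopo)

scene <- make_colony_field(
  n_per_type = c(mounding = 2, encrusting = 2, plating = 2, branching = 2),
  extent = c(7, 4), cell_size = 0.01, seed = 42)

tab  <- compute_feature_metrics(scene$grid, scene$annotations)
comm <- community_summary(tab, percent_cover(scene$annotations),
                          taxonomy = scene$annotations$taxonomy)
comm[, c("class_label", "mean_surface_complexity", "percent_cover",
         "mean_percent_slope")]
#> # A tibble: 6 × 4
#>   class_label mean_surface_complexity percent_cover mean_percent_slope
#> 1 surface                       NA             0                NA
#> 2 matrix                         1.00          1.79              0.144
#> 3 mounding                       1.23          2.02             67.6
#> 4 encrusting                     1.02          1.40             16.0
#> 5 plating                        2.03          2.02            156.
#> 6 branching                      1.35          1.40             71.2

mean_rugosity(scene$grid)
#> <rugosity_result> mean 1.0447 +/- 0.0195 S.E. over 6 transects

one_way_anova(grouped_sample(tab$surface_complexity, tab$class_label))
#> <anova_result> F(4, 5) = 6.645e+05, p = 1.698e-14
```

The mounding colonies are spherical caps whose analytic complexity is
`(a² + h²)/a² = 1.25` at the default radius 0.30 m and height 0.15 m; the
measured 1.23 reflects the 1-cm drape resolution. The class ordering —
plating and branching above mounding and encrusting, all above bare matrix
— is the structural fingerprint expected of a real reef community, and the
ANOVA confirms the classes differ.

Published class-level metrics for a surveyed 25 × 6 m Hawaiian fore-reef
plot ship with the package; cover arithmetic over them reproduces the
reported community totals:

```r
cs <- readr::read_csv(system.file("extdata", "ffs_class_summary.csv",
                                  package = "reeftopo"))
cover_totals(cs[, c("class_label", "percent_cover")], reef_taxonomy())
#> $plating_branching = 1.42  (A. cytherea + P. compressa + P. meandrina)
#> $abiotic           = 87.31 (rock/rubble + sand)
#> $dominant_coral_cover = 10.96 (P. lobata)
```

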