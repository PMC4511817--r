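Package: reeftopo
Title: Quantifying 3D Structural Complexity of Coral Reefs from Digital
    Elevation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional structural
    complexity of coral reef habitats from photogrammetry-derived digital
    elevation models (DEMs) and polygon annotations of benthic features.
    Computes per-cell slope (average-maximum technique) and combined,
    profile and planform curvature (nine-cell quadratic fit), the 3D/2D
    surface-area ratio ('surface complexity') of each annotated colony,
    linear rugosity along transect profiles, percent cover and zonal
    summaries per benthic class, and group comparisons via MANOVA, one-way
    ANOVA and Tukey's HSD. A synthetic-reef generator provides analytic
    surfaces and colony fields with closed-form ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    sp,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
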