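# Synthetic 2.5D reef scenes with analytically known structural metrics.
# A scene bundles an elevation grid, an annotation set, and a "truth" table
# holding closed-form metric values where they exist, so every pipeline
# stage can be validated without survey data.

.grid_from_fun <- function(fun, extent, cell_size, origin = c(0, 0)) {
  nc <- max(3L, round(extent[1] / cell_size))
  nr <- max(3L, round(extent[2] / cell_size))
  x <- origin[1] + (seq_len(nc) - 0.5) * cell_size
  y <- origin[2] - (seq_len(nr) - 0.5) * cell_size
  z <- outer(y, x, fun)  # rows indexed by y (north -> south)
  if (any(!is.finite(z)))
    stop("surface parameters produce non-finite elevations")
  elevation_grid(z, cell_size, origin)
}

.scene <- function(grid, annotations, truth, seed = NA_integer_,
                   params = list()) {
  structure(list(grid = grid, annotations = annotations, truth = truth,
                 seed = seed, params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d cells @ %g m, %d features, seed %s\n",
              nrow(x$grid$values), ncol(x$grid$values), x$grid$cell_size,
              length(x$annotations$features),
              ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

SYNTHETIC_TAXONOMY_LABELS <- c("surface", "matrix", "mounding", "encrusting",
                               "plating", "branching")

synthetic_taxonomy <- function() {
  taxonomy(
    class_label = SYNTHETIC_TAXONOMY_LABELS,
    biotic = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    morphotype = c("abiotic", "abiotic", "mounding", "encrusting",
                   "plating", "branching"))
}

#' Analytic test surfaces with closed-form structural metrics
#'
#' Builds a DEM sampling a named closed-form surface over a rectangular
#' extent (origin at (0, 0), x east, y ranging over `[-extent[2], 0]`), with
#' a single full-extent annotation polygon and the analytic truth values:
#' \describe{
#'   \item{flat}{`z = z0`; complexity 1, slope 0, combined curvature 0.}
#'   \item{plane}{`z = gx * x + gy * y`; percent slope
#'     `100 * sqrt(gx^2 + gy^2)`, complexity `sec(theta)`, curvature 0.}
#'   \item{dome / bowl}{`z = -+ a * r^2` about the extent centre; combined
#'     curvature `+-400 a` (z-unit scale 1), slope varies.}
#'   \item{sine_field}{`z = amp * sin(2 pi x / wavelength) *
#'     sin(2 pi y / wavelength)`; no closed-form truth recorded.}
#' }
#'
#' @param kind surface name.
#' @param params named list of surface parameters (`z0`, `gx`, `gy`, `a`,
#'   `amp`, `wavelength`).
#' @param extent `c(width, height)` in metres; default the 25 x 6 m survey
#'   plot.
#' @param cell_size cell edge in metres; default 0.005 (0.5 cm).
#' @return A `synthetic_scene`.
#' @export
make_analytic_surface <- function(kind = c("flat", "plane", "dome", "bowl",
                                           "sine_field"),
                                  params = list(),
                                  extent = c(25, 6), cell_size = 0.005) {
  kind <- match.arg(kind)
  p <- utils::modifyList(
    list(z0 = 0, gx = 1, gy = 0, a = 0.01, amp = 0.05, wavelength = 0.5),
    params)
  cx <- extent[1] / 2; cy <- -extent[2] / 2
  fun <- switch(kind,
    flat  = function(y, x) rep(p$z0, length(x)),
    plane = function(y, x) p$gx * x + p$gy * y,
    dome  = function(y, x) -p$a * ((x - cx)^2 + (y - cy)^2),
    bowl  = function(y, x)  p$a * ((x - cx)^2 + (y - cy)^2),
    sine_field = function(y, x)
      p$amp * sin(2 * pi * x / p$wavelength) * sin(2 * pi * y / p$wavelength))
  grid <- .grid_from_fun(fun, extent, cell_size)
  ext <- grid_extent(grid)
  poly <- rect_ring(ext[1], ext[2], ext[3], ext[4])
  ann <- annotation_set(
    list(annotation_feature("whole-plot", "surface", poly)),
    synthetic_taxonomy(), plot_extent = ext)
  tan_theta <- sqrt(p$gx^2 + p$gy^2)
  truth <- switch(kind,
    flat = tibble::tibble(feature_id = "whole-plot",
      surface_complexity = 1, percent_slope = 0, curv_combined = 0),
    plane = tibble::tibble(feature_id = "whole-plot",
      surface_complexity = sqrt(1 + tan_theta^2),
      percent_slope = 100 * tan_theta, curv_combined = 0),
    dome = tibble::tibble(feature_id = "whole-plot",
      surface_complexity = NA_real_, percent_slope = NA_real_,
      curv_combined = 400 * p$a),
    bowl = tibble::tibble(feature_id = "whole-plot",
      surface_complexity = NA_real_, percent_slope = NA_real_,
      curv_combined = -400 * p$a),
    sine_field = tibble::tibble(feature_id = "whole-plot",
      surface_complexity = NA_real_, percent_slope = NA_real_,
      curv_combined = NA_real_))
  .scene(grid, ann, truth, params = c(list(kind = kind), p,
                                      list(extent = extent,
                                           cell_size = cell_size)))
}

# colony elevation profiles, all returning z >= 0 additive relief ----------

# spherical cap of footprint radius a and apex height h
.cap_profile <- function(r, a, h) {
  R <- (a^2 + h^2) / (2 * h)      # sphere radius
  z <- sqrt(pmax(R^2 - r^2, 0)) - (R - h)
  ifelse(r < a, pmax(z, 0), 0)
}

# lateral (curved) surface area of the cap divided by its footprint area
cap_complexity <- function(a, h) (a^2 + h^2) / a^2

# raised disc: flat top of radius a - w, linear rim ramp of width w
.plate_profile <- function(r, a, h, w) {
  ifelse(r <= a - w, h,
         ifelse(r < a, h * (a - r) / w, 0))
}

# top disc + frustum rim over the footprint disc
plate_complexity <- function(a, h, w) {
  (pi * (a - w)^2 + pi * (2 * a - w) * sqrt(w^2 + h^2)) / (pi * a^2)
}

# low cosine-squared mound (encrusting) and high-frequency ridge field
# (branching); no closed forms recorded for these
.encrusting_profile <- function(r, a, h) ifelse(r < a, h * cos(pi * r / (2 * a))^2, 0)
.branching_profile <- function(r, dx, dy, a, h, wavelength) {
  ifelse(r < a,
         h * abs(sin(2 * pi * dx / wavelength) * sin(2 * pi * dy / wavelength)) *
           cos(pi * r / (2 * a))^2,
         0)
}

# Footprint radii are large relative to the default sub-centimetre cells so
# the two-triangle drape resolves the rim and cap geometry; heights give the
# qualitative complexity ordering plating > branching > mounding >
# encrusting observed on reef communities.
MORPHOTYPE_DEFAULTS <- list(
  mounding   = list(radius = 0.30, height = 0.15),
  encrusting = list(radius = 0.25, height = 0.04),
  plating    = list(radius = 0.30, height = 0.30, rim = 0.12),
  branching  = list(radius = 0.25, height = 0.10, wavelength = 0.06))

#' Synthetic colony field over an undulating matrix
#'
#' Places non-overlapping circular colony footprints of four morphotypes on
#' a gently undulating sand/rock matrix: mounding colonies are spherical
#' caps, encrusting ones low cosine mounds, plating ones raised discs with a
#' steep rim, branching ones high-frequency ridge fields. The truth table
#' carries closed-form surface complexity for caps
#' (`(a^2 + h^2) / a^2`) and plated discs
#' (`((a-w)^2 + (2a-w) sqrt(w^2+h^2)) / a^2`). Colony centres are drawn by
#' rejection sampling; identical `(seed, parameters)` regenerate the scene
#' bit-for-bit.
#'
#' @param n_per_type named integer vector: colonies per morphotype
#'   (`mounding`, `encrusting`, `plating`, `branching`).
#' @param extent `c(width, height)` in metres; default 25 x 6 m.
#' @param cell_size cell edge in metres; default 0.005.
#' @param seed integer seed controlling all randomness.
#' @param morphotypes shape parameters per morphotype; see
#'   `MORPHOTYPE_DEFAULTS` in the sources.
#' @param matrix_amp,matrix_wavelength amplitude (m) and wavelength (m) of
#'   the background undulation; the default 2 mm amplitude keeps the
#'   matrix near-flat so colony truth values stay valid.
#' @param n_matrix_patches number of annotated square (0.5 m) patches of
#'   bare matrix, giving the abiotic background a feature class of its own.
#' @param max_attempts rejection-sampling cap per colony.
#' @return A `synthetic_scene` whose annotations label each colony with its
#'   morphotype and matrix patches as `"matrix"`.
#' @export
make_colony_field <- function(n_per_type = c(mounding = 3, encrusting = 3,
                                             plating = 3, branching = 3),
                              extent = c(25, 6), cell_size = 0.005,
                              seed = 1L,
                              morphotypes = MORPHOTYPE_DEFAULTS,
                              matrix_amp = 0.002, matrix_wavelength = 4,
                              n_matrix_patches = 2L, max_attempts = 200L) {
  set.seed(seed)
  types <- rep(names(n_per_type), times = n_per_type)
  # square matrix patches (annotated abiotic background) join the placement
  # pool with an effective radius of half their diagonal
  patch_half <- 0.25
  types <- c(types, rep("matrix", n_matrix_patches))
  radii <- vapply(types, function(t) {
    if (t == "matrix") patch_half * sqrt(2) else morphotypes[[t]]$radius
  }, 0)
  # rejection-sample non-overlapping centres, kept clear of the plot edge
  centres <- matrix(NA_real_, length(types), 2)
  for (i in seq_along(types)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cx <- stats::runif(1, radii[i] + 2 * cell_size,
                         extent[1] - radii[i] - 2 * cell_size)
      cy <- -stats::runif(1, radii[i] + 2 * cell_size,
                          extent[2] - radii[i] - 2 * cell_size)
      if (i == 1 || all(sqrt((centres[seq_len(i - 1), 1] - cx)^2 +
                             (centres[seq_len(i - 1), 2] - cy)^2) >
                        radii[seq_len(i - 1)] + radii[i] + 4 * cell_size)) {
        centres[i, ] <- c(cx, cy); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place colony ", i, " of ", length(types),
           " without overlap after ", max_attempts,
           " attempts (placed ", i - 1, ")")
  }
  fun <- function(y, x) {
    z <- matrix_amp * sin(2 * pi * x / matrix_wavelength) *
      cos(2 * pi * y / matrix_wavelength)
    for (i in seq_along(types)) {
      if (types[i] == "matrix") next  # patches add no relief
      dx <- x - centres[i, 1]; dy <- y - centres[i, 2]
      r <- sqrt(dx^2 + dy^2)
      mp <- morphotypes[[types[i]]]
      z <- z + switch(types[i],
        mounding   = .cap_profile(r, mp$radius, mp$height),
        encrusting = .encrusting_profile(r, mp$radius, mp$height),
        plating    = .plate_profile(r, mp$radius, mp$height, mp$rim),
        branching  = .branching_profile(r, dx, dy, mp$radius, mp$height,
                                        mp$wavelength))
    }
    z
  }
  grid <- .grid_from_fun(fun, extent, cell_size)
  ext <- grid_extent(grid)
  features <- lapply(seq_along(types), function(i) {
    ring <- if (types[i] == "matrix")
      rect_ring(centres[i, 1] - patch_half, centres[i, 2] - patch_half,
                centres[i, 1] + patch_half, centres[i, 2] + patch_half)
    else
      circle_ring(centres[i, 1], centres[i, 2], radii[i], n = 96L)
    annotation_feature(
      feature_id = sprintf("%s-%02d", types[i], sum(types[seq_len(i)] == types[i])),
      class_label = types[i], exterior = ring)
  })
  ann <- annotation_set(features, synthetic_taxonomy(), plot_extent = ext)
  truth <- do.call(rbind, lapply(seq_along(types), function(i) {
    mp <- morphotypes[[types[i]]]
    tibble::tibble(
      feature_id = features[[i]]$feature_id,
      class_label = types[i],
      surface_complexity = switch(types[i],
        mounding = cap_complexity(mp$radius, mp$height),
        plating  = plate_complexity(mp$radius, mp$height, mp$rim),
        NA_real_))
  }))
  .scene(grid, ann, truth, seed = seed,
         params = list(n_per_type = n_per_type, extent = extent,
                       cell_size = cell_size, matrix_amp = matrix_amp,
                       matrix_wavelength = matrix_wavelength))
}

#' Simulated per-class metric samples for the statistics stage
#'
#' Draws normal or lognormal samples per class at specified means and
#' standard deviations, for power and type-I calibration of the
#' ANOVA/Tukey/MANOVA stage.
#'
#' @param effect_spec data frame with columns `class_label`, `mean`, `sd`
#'   (on the natural scale for `"normal"`, on the log scale for
#'   `"lognormal"`).
#' @param n features per class (single value or per-class vector).
#' @param seed integer seed.
#' @param family `"normal"` or `"lognormal"`.
#' @return A [grouped_sample()].
#' @export
make_grouped_metrics <- function(effect_spec, n, seed = 1L,
                                 family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (any(effect_spec$sd <= 0)) stop("all sds must be > 0")
  n <- rep_len(n, nrow(effect_spec))
  if (any(n < 2)) stop("need n >= 2 per group")
  set.seed(seed)
  vals <- lapply(seq_len(nrow(effect_spec)), function(i) {
    z <- stats::rnorm(n[i], effect_spec$mean[i], effect_spec$sd[i])
    if (family == "lognormal") exp(z) else z
  })
  names(vals) <- effect_spec$class_label
  structure(vals, class = "grouped_sample", transform_applied = "none")
}
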