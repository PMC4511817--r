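#' Metric raster
#'
#' A per-cell derived metric aligned cell-for-cell with its source
#' [elevation_grid()]. The one-cell border and any cell whose 3 x 3 window
#' touches nodata are `NA`. The applied sign/unit convention is carried in
#' the `convention` field so downstream comparisons are explicit.
#'
#' @param values numeric matrix.
#' @param metric_name one of `percent_slope`, `slope_degrees`,
#'   `curvature_combined`, `curvature_profile`, `curvature_planform`.
#' @param units unit string.
#' @param convention human-readable record of the convention applied.
#' @param cell_size,origin geometry inherited from the source grid.
#' @return A `metric_raster`.
#' @export
metric_raster <- function(values, metric_name, units, convention,
                          cell_size, origin) {
  ok <- c("percent_slope", "slope_degrees", "curvature_combined",
          "curvature_profile", "curvature_planform")
  if (!metric_name %in% ok)
    stop("metric_name must be one of: ", paste(ok, collapse = ", "))
  structure(
    list(values = values, metric_name = metric_name, units = units,
         convention = convention, cell_size = cell_size, origin = origin),
    class = "metric_raster")
}

#' @export
print.metric_raster <- function(x, ...) {
  cat(sprintf("<metric_raster> %s [%s], %d x %d cells @ %g m\n  convention: %s\n",
              x$metric_name, x$units, nrow(x$values), ncol(x$values),
              x$cell_size, x$convention))
  invisible(x)
}

# The nine window elevations as matrices over the interior cells.
# Z1..Z9 are numbered row-wise from the top-left of the window (Z5 centre),
# i.e. Z2 is the north neighbour and Z8 the south neighbour.
.window_stack <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3)
    stop("grid smaller than 3x3: ", nr, " x ", nc,
         " cells; derivatives need at least a 3x3 window")
  R <- 2:(nr - 1); C <- 2:(nc - 1)
  list(Z1 = m[R - 1, C - 1, drop = FALSE], Z2 = m[R - 1, C, drop = FALSE],
       Z3 = m[R - 1, C + 1, drop = FALSE], Z4 = m[R, C - 1, drop = FALSE],
       Z5 = m[R, C, drop = FALSE],         Z6 = m[R, C + 1, drop = FALSE],
       Z7 = m[R + 1, C - 1, drop = FALSE], Z8 = m[R + 1, C, drop = FALSE],
       Z9 = m[R + 1, C + 1, drop = FALSE])
}

# embed an interior-cell matrix back into the full grid with an NA border
.pad_border <- function(inner, nr, nc) {
  out <- matrix(NA_real_, nr, nc)
  out[2:(nr - 1), 2:(nc - 1)] <- inner
  out
}

#' Local quadratic surface coefficients of one 3 x 3 window
#'
#' Fits the partial quartic surface of Zevenbergen & Thorne through a cell
#' and its eight neighbours. With the window elevations Z1..Z9 numbered
#' row-wise from the top-left (Z5 the centre) and L the cell size, the
#' second-order coefficients are
#' `D = ((Z4 + Z6)/2 - Z5) / L^2`, `E = ((Z2 + Z8)/2 - Z5) / L^2`,
#' `F = (-Z1 + Z3 + Z7 - Z9) / (4 L^2)`, and the first-order gradients
#' `G = (-Z4 + Z6) / (2L)` (east), `H = (Z2 - Z8) / (2L)` (north).
#'
#' @param grid an [elevation_grid()].
#' @param row,col interior cell indices (1-based).
#' @return A list with components `D`, `E`, `F` (1/m), `G`, `H`
#'   (dimensionless), and `window_center = c(row, col)`.
#' @export
fit_quadratic_window <- function(grid, row, col) {
  m <- grid$values
  if (row < 2 || row > nrow(m) - 1 || col < 2 || col > ncol(m) - 1)
    stop("(", row, ", ", col, ") is not an interior cell")
  w <- m[(row - 1):(row + 1), (col - 1):(col + 1)]
  if (anyNA(w))
    stop("incomplete window: 3x3 neighbourhood of (", row, ", ", col,
         ") contains nodata")
  L <- grid$cell_size
  Z <- as.vector(t(w))  # Z1..Z9 row-wise
  list(D = ((Z[4] + Z[6]) / 2 - Z[5]) / L^2,
       E = ((Z[2] + Z[8]) / 2 - Z[5]) / L^2,
       F = (-Z[1] + Z[3] + Z[7] - Z[9]) / (4 * L^2),
       G = (-Z[4] + Z[6]) / (2 * L),
       H = (Z[2] - Z[8]) / (2 * L),
       window_center = c(row, col))
}

#' Slope raster by the average-maximum technique
#'
#' Gradient components are the weighted third-order finite differences over
#' the 3 x 3 window (Horn's method):
#' `dz/dx = ((Z3 + 2 Z6 + Z9) - (Z1 + 2 Z4 + Z7)) / (8L)` and
#' `dz/dy = ((Z1 + 2 Z2 + Z3) - (Z7 + 2 Z8 + Z9)) / (8L)`.
#' The slope of the fitted plane is `tan(theta) = sqrt((dz/dx)^2 + (dz/dy)^2)`;
#' percent slope is `tan(theta) * 100` (so a 45 degree plane is 100%). The
#' method is exact on planar surfaces.
#'
#' @param grid an [elevation_grid()] with at least 3 rows and columns.
#' @param units `"percent"` (default, tangent x 100) or `"degrees"`.
#' @return A [metric_raster()].
#' @export
slope_raster <- function(grid, units = c("percent", "degrees")) {
  units <- match.arg(units)
  w <- .window_stack(grid$values)
  L <- grid$cell_size
  dzdx <- ((w$Z3 + 2 * w$Z6 + w$Z9) - (w$Z1 + 2 * w$Z4 + w$Z7)) / (8 * L)
  dzdy <- ((w$Z1 + 2 * w$Z2 + w$Z3) - (w$Z7 + 2 * w$Z8 + w$Z9)) / (8 * L)
  tan_theta <- sqrt(dzdx^2 + dzdy^2)
  vals <- if (units == "percent") tan_theta * 100 else atan(tan_theta) * 180 / pi
  metric_raster(
    .pad_border(vals, nrow(grid$values), ncol(grid$values)),
    metric_name = if (units == "percent") "percent_slope" else "slope_degrees",
    units = if (units == "percent") "percent (rise/run x 100)" else "degrees",
    convention = "average-maximum (Horn 8-point weighted difference); border and incomplete windows masked",
    cell_size = grid$cell_size, origin = grid$origin)
}

#' Curvature rasters from the nine-cell quadratic fit
#'
#' Per cell, the Zevenbergen-Thorne coefficients (see
#' [fit_quadratic_window()]) give three curvature measures, each scaled by
#' -100 so that positive combined curvature means a convex (dome-like) form:
#' \itemize{
#'   \item combined: `-2 (D + E) * 100` — the overall second derivative;
#'   \item profile: `2 (D G^2 + E H^2 + F G H) / (G^2 + H^2) * 100` —
#'     curvature parallel to the maximum-slope direction (negative = convex);
#'   \item planform: `-2 (D H^2 + E G^2 - F G H) / (G^2 + H^2) * 100` —
#'     curvature perpendicular to it (positive = convex).
#' }
#' On level cells (`G = H = 0`) profile and planform are defined as 0.
#' Output units are 1/100 of the z-unit per map unit; `z_unit_scale`
#' multiplies all three outputs to re-express them at another reference
#' z-unit (it defaults to 1 and is never applied implicitly).
#'
#' @param grid an [elevation_grid()] with at least 3 rows and columns.
#' @param z_unit_scale positive multiplicative rescaling of the outputs.
#' @return A list of three [metric_raster()]s: `combined`, `profile`,
#'   `planform`.
#' @export
curvature_raster <- function(grid, z_unit_scale = 1) {
  if (!is.numeric(z_unit_scale) || length(z_unit_scale) != 1 ||
      z_unit_scale <= 0)
    stop("z_unit_scale must be a single positive number")
  w <- .window_stack(grid$values)
  L <- grid$cell_size
  D <- ((w$Z4 + w$Z6) / 2 - w$Z5) / L^2
  E <- ((w$Z2 + w$Z8) / 2 - w$Z5) / L^2
  F <- (-w$Z1 + w$Z3 + w$Z7 - w$Z9) / (4 * L^2)
  G <- (-w$Z4 + w$Z6) / (2 * L)
  H <- (w$Z2 - w$Z8) / (2 * L)
  g2 <- G^2 + H^2
  combined <- -2 * (D + E) * 100
  profile  <- ifelse(g2 == 0, 0,  2 * (D * G^2 + E * H^2 + F * G * H) / g2 * 100)
  planform <- ifelse(g2 == 0, 0, -2 * (D * H^2 + E * G^2 - F * G * H) / g2 * 100)
  # NA windows propagate through the arithmetic; level-cell ifelse keeps them
  profile[is.na(combined)] <- NA_real_
  planform[is.na(combined)] <- NA_real_
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  conv <- sprintf(
    "Zevenbergen-Thorne 9-cell fit, x(-100) so convex combined is positive; z_unit_scale = %g",
    z_unit_scale)
  mk <- function(v, name) metric_raster(
    .pad_border(v * z_unit_scale, nr, nc), metric_name = name,
    units = "1/100 z-unit per map unit", convention = conv,
    cell_size = grid$cell_size, origin = grid$origin)
  list(combined = mk(combined, "curvature_combined"),
       profile  = mk(profile,  "curvature_profile"),
       planform = mk(planform, "curvature_planform"))
}
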