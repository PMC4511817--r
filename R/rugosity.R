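# Bilinear interpolation of cell-centre elevations at arbitrary points.
# Points outside the cell-centre lattice hull (the outer half-cell ring)
# are clamped onto it. NA if any contributing cell is nodata.
.bilinear <- function(grid, x, y) {
  cx <- cell_center_x(grid); cy <- cell_center_y(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  x <- pmin(pmax(x, cx[1]), cx[nc])
  y <- pmin(pmax(y, cy[nr]), cy[1])
  fc <- (x - cx[1]) / grid$cell_size          # fractional column offset
  fr <- (cy[1] - y) / grid$cell_size          # fractional row offset
  c0 <- pmin(floor(fc) + 1, nc - 1); r0 <- pmin(floor(fr) + 1, nr - 1)
  tx <- fc - (c0 - 1); ty <- fr - (r0 - 1)
  v <- grid$values
  z00 <- v[cbind(r0, c0)];     z01 <- v[cbind(r0, c0 + 1)]
  z10 <- v[cbind(r0 + 1, c0)]; z11 <- v[cbind(r0 + 1, c0 + 1)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}

#' Extract an elevation profile along a straight transect
#'
#' Stations are sampled at uniform chainage spacing — the largest spacing
#' not exceeding `step` (default one cell size) that divides the transect
#' length evenly, so both endpoints are stations and the trace is invariant
#' to direction reversal. Elevations are bilinearly interpolated from
#' cell-centre values. A transect crossing nodata fails with the first bad
#' chainage.
#'
#' @param grid an [elevation_grid()].
#' @param start,end numeric `(x, y)` in local planar metres, inside the grid
#'   extent.
#' @param step station spacing in metres; default `grid$cell_size`.
#' @return A `profile_trace`: list with `stations` (tibble of `chainage`,
#'   `elevation`) and `transect` (start/end).
#' @export
extract_profile <- function(grid, start, end, step = grid$cell_size) {
  if (step <= 0) stop("step must be > 0")
  ext <- grid_extent(grid)
  for (p in list(start, end))
    if (p[1] < ext[1] || p[1] > ext[3] || p[2] < ext[2] || p[2] > ext[4])
      stop("transect endpoint (", p[1], ", ", p[2],
           ") outside grid extent [", ext[1], ", ", ext[3], "] x [",
           ext[2], ", ", ext[4], "]")
  len <- sqrt(sum((end - start)^2))
  if (len == 0) stop("transect has zero length")
  # uniform station spacing <= step that divides the transect evenly, so the
  # trace (and hence the rugosity index) is invariant to direction reversal
  n_seg <- max(1L, ceiling(len / step - 1e-9))
  chain <- seq(0, len, length.out = n_seg + 1L)
  t <- chain / len
  x <- start[1] + t * (end[1] - start[1])
  y <- start[2] + t * (end[2] - start[2])
  z <- .bilinear(grid, x, y)
  if (anyNA(z))
    stop("transect crosses nodata at chainage ",
         signif(chain[which(is.na(z))[1]], 6), " m")
  structure(
    list(stations = tibble::tibble(chainage = chain, elevation = z),
         transect = list(start = start, end = end)),
    class = "profile_trace")
}

#' Rugosity index of a profile trace
#'
#' Path distance along the profile (accounting for vertical relief) divided
#' by the straight-line chainage:
#' `sum(sqrt(dc^2 + dz^2)) / total_chainage`, always `>= 1` and exactly 1
#' for a level profile.
#'
#' @param trace a `profile_trace` from [extract_profile()].
#' @return The dimensionless rugosity index.
#' @export
rugosity_index <- function(trace) {
  s <- trace$stations
  if (nrow(s) < 2) stop("profile needs at least 2 stations")
  dc <- diff(s$chainage); dz <- diff(s$elevation)
  sum(sqrt(dc^2 + dz^2)) / sum(dc)
}

#' Default six-transect plan
#'
#' Two long-axis transects (at 1/3 and 2/3 of the plot width), two
#' short-axis transects (at 1/3 and 2/3 of the length) and the two
#' corner-to-corner diagonals, expressed in fractional coordinates of the
#' cell-centre lattice (0 = first cell centre, 1 = last).
#'
#' @return A list of transects, each `list(start = c(fx, fy), end = c(fx, fy))`.
#' @export
default_transect_plan <- function() {
  list(
    list(start = c(0, 1 / 3), end = c(1, 1 / 3)),
    list(start = c(0, 2 / 3), end = c(1, 2 / 3)),
    list(start = c(1 / 3, 0), end = c(1 / 3, 1)),
    list(start = c(2 / 3, 0), end = c(2 / 3, 1)),
    list(start = c(0, 0), end = c(1, 1)),
    list(start = c(0, 1), end = c(1, 0)))
}

# fractional lattice coordinates -> planar coordinates on the centre hull
.plan_to_xy <- function(grid, f) {
  cx <- cell_center_x(grid); cy <- cell_center_y(grid)
  c(cx[1] + f[1] * (cx[length(cx)] - cx[1]),
    cy[length(cy)] + f[2] * (cy[1] - cy[length(cy)]))
}

#' Mean rugosity over a transect plan
#'
#' Computes the rugosity index along each transect of the plan and returns
#' per-transect indices with their mean and standard error. Transects that
#' fail extraction (nodata crossing) are flagged and excluded; at least two
#' must survive.
#'
#' @param grid an [elevation_grid()].
#' @param plan list of transects in fractional plot coordinates; default
#'   [default_transect_plan()].
#' @param step station spacing in metres; default one cell size.
#' @return A `rugosity_result`: list with `per_transect` (tibble), `mean_rugosity`,
#'   `se_rugosity`, `n_used`.
#' @export
mean_rugosity <- function(grid, plan = default_transect_plan(),
                          step = grid$cell_size) {
  if (length(plan) < 2) stop("transect plan needs at least 2 transects")
  rows <- lapply(seq_along(plan), function(i) {
    tr <- plan[[i]]
    start <- .plan_to_xy(grid, tr$start); end <- .plan_to_xy(grid, tr$end)
    ri <- tryCatch(rugosity_index(extract_profile(grid, start, end, step)),
                   error = function(e) NA_real_)
    tibble::tibble(
      transect = i,
      x0 = start[1], y0 = start[2], x1 = end[1], y1 = end[2],
      rugosity = ri, flagged = is.na(ri))
  })
  per <- do.call(rbind, rows)
  ok <- per$rugosity[!per$flagged]
  if (length(ok) < 2)
    stop("fewer than 2 transects usable (", length(ok), " of ",
         length(plan), ")")
  structure(
    list(per_transect = per,
         mean_rugosity = mean(ok),
         se_rugosity = stats::sd(ok) / sqrt(length(ok)),
         n_used = length(ok)),
    class = "rugosity_result")
}

#' @export
print.rugosity_result <- function(x, ...) {
  cat(sprintf("<rugosity_result> mean %.4f +/- %.4f S.E. over %d transects\n",
              x$mean_rugosity, x$se_rugosity, x$n_used))
  invisible(x)
}
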