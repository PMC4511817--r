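#' Planimetric (2D) area of a feature polygon
#'
#' Exact vector area of the exterior ring minus any holes, independent of
#' the raster.
#'
#' @param feature an [annotation_feature()].
#' @return Area in square metres.
#' @export
planimetric_area <- function(feature) {
  a <- polygon_area(feature$polygon)
  if (a <= 0)
    stop("feature ", feature$feature_id, ": degenerate polygon (area 0)")
  a
}

# Corner elevations of the cell lattice: entry (i, j) of an (nr+1) x (nc+1)
# matrix is the mean of the <= 4 adjacent cell-centre elevations.
.corner_elevations <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  padded <- matrix(NA_real_, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- values
  idx_r <- seq_len(nr + 1); idx_c <- seq_len(nc + 1)
  q <- list(padded[idx_r, idx_c, drop = FALSE],
            padded[idx_r, idx_c + 1, drop = FALSE],
            padded[idx_r + 1, idx_c, drop = FALSE],
            padded[idx_r + 1, idx_c + 1, drop = FALSE])
  total <- matrix(0, nr + 1, nc + 1)
  count <- matrix(0, nr + 1, nc + 1)
  for (m in q) {
    valid <- !is.na(m)
    total[valid] <- total[valid] + m[valid]
    count <- count + valid
  }
  out <- total / count
  out[count == 0] <- NA_real_
  out
}

# logical matrix: cell centre inside the feature polygon
.cells_in_feature <- function(grid, feature) {
  cx <- cell_center_x(grid); cy <- cell_center_y(grid)
  ext <- feature$polygon$exterior
  # restrict the point-in-polygon test to the polygon's bounding box
  cr <- range(ext[, 1]); rr <- range(ext[, 2])
  cols <- which(cx >= cr[1] - grid$cell_size & cx <= cr[2] + grid$cell_size)
  rows <- which(cy >= rr[1] - grid$cell_size & cy <= rr[2] + grid$cell_size)
  inside <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (length(rows) == 0 || length(cols) == 0) return(inside)
  px <- rep(cx[cols], each = length(rows))
  py <- rep(cy[rows], times = length(cols))
  hit <- points_in_polygon(px, py, feature$polygon)
  inside[rows, cols] <- hit
  inside
}

# 3D area of the two-triangle drape over a set of cells (logical matrix),
# corner elevations precomputed. Diagonal fixed top-left -> bottom-right.
.drape_area <- function(corners, cells, cell_size) {
  idx <- which(cells, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  r <- idx[, 1]; c <- idx[, 2]
  z_tl <- corners[cbind(r, c)]
  z_tr <- corners[cbind(r, c + 1)]
  z_bl <- corners[cbind(r + 1, c)]
  z_br <- corners[cbind(r + 1, c + 1)]
  L <- cell_size
  # triangle (TL, TR, BR): edge vectors u = TR-TL = (L, 0, dz1),
  # v = BR-TL = (L, -L, dz2); area = |u x v| / 2
  tri_area <- function(ux, uy, uz, vx, vy, vz) {
    cxp <- uy * vz - uz * vy
    cyp <- uz * vx - ux * vz
    czp <- ux * vy - uy * vx
    sqrt(cxp^2 + cyp^2 + czp^2) / 2
  }
  a1 <- tri_area(L, 0, z_tr - z_tl, L, -L, z_br - z_tl)
  a2 <- tri_area(L, -L, z_br - z_tl, 0, -L, z_bl - z_tl)
  sum(a1 + a2)
}

#' Draped (3D) surface area and surface complexity of one feature
#'
#' The DEM restricted to cells whose centres fall inside the feature polygon
#' is triangulated: each cell is split into two triangles along the fixed
#' top-left to bottom-right diagonal, on corner elevations interpolated as
#' the mean of the (up to four) adjacent cell centres. `area_3d` is the sum
#' of 3D triangle areas; `area_2d` is the rasterised planimetric area
#' `n_cells * cell_size^2`, so the surface-complexity ratio
#' `area_3d / area_2d >= 1` compares like with like. The drape cannot
#' represent overhangs: for plating morphologies the reported area is that
#' of the 2.5D drape surface.
#'
#' @param grid an [elevation_grid()].
#' @param feature an [annotation_feature()].
#' @param corners optional precomputed corner-elevation lattice (internal
#'   reuse across features).
#' @return A list (`surface_area_result`) with `area_2d`, `area_3d`,
#'   `surface_complexity`, `n_cells`.
#' @export
surface_area_3d <- function(grid, feature, corners = NULL) {
  cells <- .cells_in_feature(grid, feature) & !is.na(grid$values)
  n <- sum(cells)
  if (n == 0)
    stop("feature ", feature$feature_id, " below raster resolution: ",
         "polygon area ", signif(polygon_area(feature$polygon), 6),
         " m^2 contains no cell centre at cell size ", grid$cell_size, " m")
  if (is.null(corners)) corners <- .corner_elevations(grid$values)
  a3 <- .drape_area(corners, cells, grid$cell_size)
  a2 <- n * grid$cell_size^2
  structure(
    list(area_2d = a2, area_3d = a3, surface_complexity = a3 / a2,
         n_cells = n),
    class = "surface_area_result")
}

#' Surface complexity for every feature of an annotation set
#'
#' Features whose polygon captures no cell centre (below raster resolution)
#' are flagged with `NA` metrics rather than dropped.
#'
#' @param grid an [elevation_grid()].
#' @param annotations an [annotation_set()].
#' @return A `tibble` with one row per feature: `feature_id`, `class_label`,
#'   `area_2d_m2` (vector polygon area), `area_3d_m2`, `surface_complexity`,
#'   `n_cells`, `flagged`.
#' @export
surface_complexity_table <- function(grid, annotations) {
  if (length(annotations$features) == 0)
    stop("annotation set is empty")
  corners <- .corner_elevations(grid$values)  # shared across features
  rows <- lapply(annotations$features, function(f) {
    res <- tryCatch(surface_area_3d(grid, f, corners = corners),
                    error = function(e) NULL)
    tibble::tibble(
      feature_id = f$feature_id,
      class_label = f$class_label,
      area_2d_m2 = polygon_area(f$polygon),
      area_3d_m2 = if (is.null(res)) NA_real_ else res$area_3d,
      surface_complexity = if (is.null(res)) NA_real_ else res$surface_complexity,
      n_cells = if (is.null(res)) 0L else as.integer(res$n_cells),
      flagged = is.null(res))
  })
  do.call(rbind, rows)
}
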