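#' Elevation grid
#'
#' A regular, square-celled grid of elevations in metres (up-positive) on a
#' local planar coordinate system. Rows run north to south: cell `(r, c)` has
#' its centre at `origin + ((c - 0.5) * cell_size, -(r - 0.5) * cell_size)`,
#' with `origin` the outer corner of the top-left cell. Missing cells are
#' `NA`.
#'
#' @param values numeric matrix of elevations (m); `NA` marks nodata.
#' @param cell_size edge length of a (square) cell in metres.
#' @param origin numeric length-2, `(x, y)` of the outer top-left corner.
#' @return An object of class `elevation_grid`.
#' @export
elevation_grid <- function(values, cell_size, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number (metres)")
  if (length(origin) != 2 || anyNA(origin))
    stop("`origin` must be (x, y) in local planar metres")
  if (any(!is.finite(values[!is.na(values)])))
    stop("all non-missing elevations must be finite")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  elevation range: [%g, %g] m, %d nodata cells\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname elevation_grid
#' @param grid an `elevation_grid`.
#' @export
nodata_mask <- function(grid) is.na(grid$values)

# x/y coordinates of all cell centres (vectors of length ncol / nrow)
cell_center_x <- function(grid) {
  grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size
}
cell_center_y <- function(grid) {
  grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size
}

# extent rectangle c(xmin, ymin, xmax, ymax) of the grid's outer edges
grid_extent <- function(grid) {
  c(grid$origin[1],
    grid$origin[2] - nrow(grid$values) * grid$cell_size,
    grid$origin[1] + ncol(grid$values) * grid$cell_size,
    grid$origin[2])
}

#' Benthic class taxonomy
#'
#' A taxonomy declares the admissible class labels, whether each is living
#' coral or abiotic substrate, and its gross growth form ("morphotype").
#'
#' @param class_label character vector of class names.
#' @param biotic logical; `TRUE` for living coral classes.
#' @param morphotype character; one of `"plating"`, `"branching"`,
#'   `"mounding"`, `"encrusting"`, `"abiotic"`.
#' @return A `tibble` with one row per class.
#' @export
taxonomy <- function(class_label, biotic,
                     morphotype = ifelse(biotic, "mounding", "abiotic")) {
  stopifnot(length(class_label) == length(biotic))
  if (anyDuplicated(class_label))
    stop("duplicated class labels in taxonomy")
  ok <- c("plating", "branching", "mounding", "encrusting", "abiotic")
  if (!all(morphotype %in% ok))
    stop("morphotype must be one of: ", paste(ok, collapse = ", "))
  tibble::tibble(class_label = as.character(class_label),
                 biotic = as.logical(biotic),
                 morphotype = as.character(morphotype))
}

#' Default benthic taxonomy of a Hawaiian fore-reef survey plot
#'
#' The six scleractinian species and two abiotic substrate classes of the
#' French Frigate Shoals survey plot used throughout the package examples.
#'
#' @return A taxonomy `tibble` (see [taxonomy()]).
#' @export
reef_taxonomy <- function() {
  taxonomy(
    class_label = c("A. cytherea", "M. capitata", "M. patula", "P. compressa",
                    "P. lobata", "P. meandrina", "rock/rubble", "sand"),
    biotic = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    morphotype = c("plating", "encrusting", "encrusting", "branching",
                   "mounding", "branching", "abiotic", "abiotic"))
}

#' Annotation feature and annotation set
#'
#' An annotation feature is one digitized benthic element: a polygon (one
#' exterior ring, optional holes) with a class label. An annotation set
#' catalogues all features of a plot together with the taxonomy and the
#' plot extent.
#'
#' @param feature_id unique identifier string.
#' @param class_label class name; must be present in the taxonomy.
#' @param exterior two-column matrix of (x, y) vertices in metres.
#' @param holes list of hole rings (same format), possibly empty.
#' @return `annotation_feature()` returns an `annotation_feature`;
#'   `annotation_set()` an `annotation_set`.
#' @export
annotation_feature <- function(feature_id, class_label, exterior,
                               holes = list()) {
  exterior <- .open_ring(as.matrix(exterior))
  if (nrow(exterior) < 3)
    stop("feature ", feature_id, ": exterior ring needs >= 3 vertices")
  if (!ring_is_simple(exterior))
    stop("feature ", feature_id, ": exterior ring is self-intersecting")
  if (ring_area(exterior) <= 0)
    stop("feature ", feature_id, ": exterior ring has zero area")
  holes <- lapply(holes, function(h) .open_ring(as.matrix(h)))
  structure(
    list(feature_id = as.character(feature_id),
         class_label = as.character(class_label),
         polygon = list(exterior = exterior, holes = holes)),
    class = "annotation_feature")
}

#' @rdname annotation_feature
#' @param features list of `annotation_feature` objects.
#' @param taxonomy a taxonomy `tibble` ([taxonomy()]).
#' @param plot_extent `c(xmin, ymin, xmax, ymax)` of the surveyed plot in
#'   metres; defaults to the bounding box of the features.
#' @export
annotation_set <- function(features, taxonomy, plot_extent = NULL) {
  ids <- vapply(features, `[[`, "", "feature_id")
  if (anyDuplicated(ids))
    stop("duplicated feature_id: ", ids[duplicated(ids)][1])
  labels <- vapply(features, `[[`, "", "class_label")
  unknown <- setdiff(labels, taxonomy$class_label)
  if (length(unknown) > 0)
    stop("class label(s) not in taxonomy: ",
         paste(sQuote(unknown), collapse = ", "),
         "; taxonomy declares: ",
         paste(sQuote(taxonomy$class_label), collapse = ", "))
  if (is.null(plot_extent)) {
    xs <- unlist(lapply(features, function(f) f$polygon$exterior[, 1]))
    ys <- unlist(lapply(features, function(f) f$polygon$exterior[, 2]))
    plot_extent <- c(min(xs), min(ys), max(xs), max(ys))
  }
  structure(
    list(features = features, taxonomy = taxonomy,
         plot_extent = as.numeric(plot_extent)),
    class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d features, %d classes, extent %g x %g m\n",
              length(x$features), nrow(x$taxonomy),
              x$plot_extent[3] - x$plot_extent[1],
              x$plot_extent[4] - x$plot_extent[2]))
  invisible(x)
}

# biotic flag of one feature, looked up from the taxonomy
feature_biotic <- function(feature, taxonomy) {
  taxonomy$biotic[match(feature$class_label, taxonomy$class_label)]
}

#' Read a DEM from a single-band GeoTIFF
#'
#' The file must be a single-band, uncompressed GeoTIFF with square cells and
#' an unrotated affine transform; any CRS tag is ignored (coordinates are
#' treated as local planar metres). Cells equal to the file's declared nodata
#' sentinel become `NA`.
#'
#' @param path path to the GeoTIFF.
#' @param depth_mode when `TRUE`, input values are depths (down-positive) and
#'   are negated on load so the grid stores up-positive elevation.
#' @return An [elevation_grid()].
#' @export
load_dem <- function(path, depth_mode = FALSE) {
  g <- read_geotiff(path)
  if (abs(g$cell_size_x - g$cell_size_y) >
      1e-9 * max(abs(g$cell_size_x), abs(g$cell_size_y)))
    stop("non-square cells not supported: dx = ", g$cell_size_x,
         " m, dy = ", g$cell_size_y, " m")
  v <- g$values
  if (!is.na(g$nodata)) v[v == g$nodata] <- NA_real_
  if (isTRUE(depth_mode)) v <- -v
  elevation_grid(v, cell_size = g$cell_size_x, origin = g$origin)
}

#' Write an elevation or metric grid to GeoTIFF
#'
#' @param grid an [elevation_grid()] or [metric_raster].
#' @param path output path.
#' @param nodata finite sentinel written in place of `NA` cells and declared
#'   in the GeoTIFF nodata tag.
#' @return `path`, invisibly.
#' @export
write_dem <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nd <- if (anyNA(v)) nodata else NULL
  write_geotiff(v, path, cell_size = grid$cell_size, origin = grid$origin,
                nodata = nd, dtype = "float64")
  invisible(path)
}

.ring_from_coords <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  .open_ring(m)
}

#' Read benthic annotations from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection` of `Polygon`/`MultiPolygon` features,
#' each carrying a `class` property (a `feature_id`/`id` property is used
#' when present, otherwise ids are generated). MultiPolygons are split into
#' one feature per part, suffixed `-1`, `-2`, .... Labels absent from the
#' taxonomy are rejected.
#'
#' @param path path to a GeoJSON file.
#' @param taxonomy a taxonomy `tibble` ([taxonomy()]).
#' @param plot_extent optional plot rectangle `c(xmin, ymin, xmax, ymax)`.
#' @return An [annotation_set()].
#' @export
load_annotations <- function(path, taxonomy, plot_extent = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("GeoJSON file is not a FeatureCollection: ", path)
  features <- list()
  auto <- 0L
  for (f in gj$features) {
    props <- f$properties
    label <- props[["class"]]
    if (is.null(label)) stop("feature without a \"class\" property in ", path)
    fid <- props[["feature_id"]]
    if (is.null(fid)) fid <- props[["id"]]
    if (is.null(fid)) { auto <- auto + 1L; fid <- sprintf("F%04d", auto) }
    geom <- f$geometry
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type ", geom$type, " in ", path))
    multi <- length(parts) > 1
    for (k in seq_along(parts)) {
      rings <- lapply(parts[[k]], .ring_from_coords)
      pid <- if (multi) paste0(fid, "-", k) else as.character(fid)
      features[[length(features) + 1L]] <- annotation_feature(
        feature_id = pid, class_label = label,
        exterior = rings[[1]],
        holes = if (length(rings) > 1) rings[-1] else list())
    }
  }
  labels <- vapply(features, `[[`, "", "class_label")
  unknown <- setdiff(labels, taxonomy$class_label)
  if (length(unknown) > 0)
    stop("class label(s) not in taxonomy: ",
         paste(sQuote(unknown), collapse = ", "),
         "; taxonomy declares: ",
         paste(sQuote(taxonomy$class_label), collapse = ", "))
  annotation_set(features, taxonomy, plot_extent = plot_extent)
}

#' Write annotations to GeoJSON
#'
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  feat <- lapply(annotations$features, function(f) {
    rings <- c(list(f$polygon$exterior), f$polygon$holes)
    coords <- lapply(rings, function(r) {
      r <- .close_ring(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(feature_id = f$feature_id, class = f$class_label),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

FEATURE_TABLE_COLUMNS <- c(
  "feature_id", "class_label", "area_2d_m2", "area_3d_m2",
  "surface_complexity", "n_cells", "mean_percent_slope", "se_percent_slope",
  "mean_curv_combined", "se_curv_combined", "mean_curv_profile",
  "se_curv_profile", "mean_curv_planform", "se_curv_planform")

#' Write / read the per-feature metrics table
#'
#' One row per annotated feature, fixed column order
#' (`feature_id, class_label, area_2d_m2, area_3d_m2, surface_complexity,
#' n_cells, mean_percent_slope, se_percent_slope, mean_curv_combined,
#' se_curv_combined, mean_curv_profile, se_curv_profile, mean_curv_planform,
#' se_curv_planform`), full double precision, missing values as empty fields.
#'
#' @param table a feature metrics `tibble`.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(table, path) {
  for (col in FEATURE_TABLE_COLUMNS)
    if (!col %in% names(table))
      table[[col]] <- if (col %in% c("feature_id", "class_label"))
        character(nrow(table)) else NA_real_
  table <- table[, FEATURE_TABLE_COLUMNS]
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      feature_id = readr::col_character(),
      class_label = readr::col_character(),
      n_cells = readr::col_integer(),
      .default = readr::col_double()))
}
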