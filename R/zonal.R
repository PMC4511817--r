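# standard error with the n-1 denominator; NA when n < 2
.se <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

#' Rasterize an annotation partition
#'
#' Assigns every cell to at most one feature by cell-centre membership
#' (even-odd rule with the half-open tie direction used throughout the
#' package). Features claiming the same cell raise an error: the annotation
#' layer must be a partition.
#'
#' @param grid an [elevation_grid()].
#' @param annotations an [annotation_set()].
#' @return A `label_grid`: list with `labels` (integer matrix, 0 =
#'   background, i = i-th feature), `feature_ids`, and `flagged_features`
#'   (ids that captured zero cells).
#' @export
rasterize_partition <- function(grid, annotations) {
  labels <- matrix(0L, nrow(grid$values), ncol(grid$values))
  ids <- vapply(annotations$features, `[[`, "", "feature_id")
  flagged <- character(0)
  for (i in seq_along(annotations$features)) {
    f <- annotations$features[[i]]
    cells <- .cells_in_feature(grid, f)
    clash <- cells & labels != 0L
    if (any(clash)) {
      cell <- which(clash, arr.ind = TRUE)[1, ]
      stop("overlapping polygons: features ", sQuote(ids[labels[clash][1]]),
           " and ", sQuote(f$feature_id), " both claim cell (",
           cell[1], ", ", cell[2], ")")
    }
    if (!any(cells)) flagged <- c(flagged, f$feature_id)
    labels[cells] <- i
  }
  structure(list(labels = labels, feature_ids = ids,
                 flagged_features = flagged),
            class = "label_grid")
}

#' Per-feature summary of a metric raster
#'
#' Mean and standard error (`sd / sqrt(n)`, n-1 denominator) of the metric
#' over each feature's unmasked cells. Features with zero unmasked cells are
#' flagged; the SE is missing (`NA`), never 0, when fewer than two cells
#' contribute.
#'
#' @param label_grid result of [rasterize_partition()].
#' @param metric a [metric_raster()] aligned with the label grid.
#' @return A `tibble`: `feature_id`, `mean`, `se`, `n_cells`, `flagged`.
#' @export
feature_summary <- function(label_grid, metric) {
  if (!all(dim(label_grid$labels) == dim(metric$values)))
    stop("label grid and metric raster are not aligned")
  lab <- as.vector(label_grid$labels)
  val <- as.vector(metric$values)
  keep <- lab != 0L & !is.na(val)
  rows <- lapply(seq_along(label_grid$feature_ids), function(i) {
    v <- val[keep & lab == i]
    tibble::tibble(
      feature_id = label_grid$feature_ids[i],
      mean = if (length(v) == 0) NA_real_ else mean(v),
      se = .se(v),
      n_cells = length(v),
      flagged = length(v) == 0)
  })
  do.call(rbind, rows)
}

#' Percent cover per benthic class
#'
#' Vector (polygon) areas, clipped to the plot extent, as a percentage of
#' the plot area. Every taxonomy class appears, possibly with zero cover.
#' Clipping that removes area is reported via a warning.
#'
#' @param annotations an [annotation_set()] with a defined `plot_extent`.
#' @return A `tibble`: `class_label`, `area_m2`, `percent_cover`.
#' @export
percent_cover <- function(annotations) {
  ext <- annotations$plot_extent
  plot_area <- (ext[3] - ext[1]) * (ext[4] - ext[2])
  if (plot_area <= 0) stop("plot_extent has zero area")
  areas <- stats::setNames(numeric(nrow(annotations$taxonomy)),
                           annotations$taxonomy$class_label)
  clipped_away <- 0
  for (f in annotations$features) {
    a_full <- polygon_area(f$polygon)
    a_clip <- clipped_polygon_area(f$polygon, ext)
    clipped_away <- clipped_away + (a_full - a_clip)
    areas[f$class_label] <- areas[f$class_label] + a_clip
  }
  if (clipped_away > 1e-12 * plot_area)
    warning("features extend beyond plot_extent; ",
            signif(clipped_away, 6), " m^2 clipped away")
  tibble::tibble(
    class_label = names(areas),
    area_m2 = unname(areas),
    percent_cover = unname(areas) / plot_area * 100)
}

# Pooled (cell-level) class statistics reconstructed exactly from per-feature
# (mean, se, n): per feature, sum = mean*n and sum of squares
# ss = se^2 * n * (n-1) + n * mean^2.
.pooled_class_stats <- function(mean, se, n) {
  keep <- !is.na(mean) & n > 0
  mean <- mean[keep]; se <- se[keep]; n <- n[keep]
  N <- sum(n)
  if (N == 0) return(c(mean = NA_real_, se = NA_real_, n = 0))
  s1 <- sum(mean * n)
  ss_within <- ifelse(n < 2 | is.na(se), 0, se^2 * n * (n - 1))
  s2 <- sum(ss_within + n * mean^2)
  mu <- s1 / N
  if (N < 2) return(c(mean = mu, se = NA_real_, n = N))
  var_pooled <- (s2 - N * mu^2) / (N - 1)
  c(mean = mu, se = sqrt(max(var_pooled, 0) / N), n = N)
}

#' Community-level summary per benthic class
#'
#' Reproduces the structure of a per-class structural-metrics table:
#' surface complexity and percent slope are summarised over features (the
#' colony is the replicate); curvature statistics are pooled over cells
#' within each class (reconstructed exactly from the per-feature mean, SE
#' and cell count). Percent covers are attached. SEs are missing, not zero,
#' when fewer than two replicates contribute.
#'
#' @param table per-feature metrics `tibble` (see [compute_feature_metrics()]
#'   or [read_feature_table()]).
#' @param covers per-class percent cover `tibble` from [percent_cover()].
#' @param taxonomy taxonomy `tibble`; defaults to the classes present in
#'   `covers`.
#' @return A `tibble`, one row per class, columns ordered surface
#'   complexity, percent cover, percent slope, combined/profile/planform
#'   curvature (mean and SE each), plus `n_features`.
#' @export
community_summary <- function(table, covers, taxonomy = NULL) {
  classes <- if (!is.null(taxonomy)) taxonomy$class_label
             else covers$class_label
  rows <- lapply(classes, function(cl) {
    t <- table[!is.na(table$class_label) & table$class_label == cl, ]
    sc <- t$surface_complexity[!is.na(t$surface_complexity)]
    # slope: feature-level replicates
    sl <- t$mean_percent_slope[!is.na(t$mean_percent_slope)]
    # curvature pooling needs the cell count the curvature stats were
    # computed over (border cells are masked); fall back to n_cells for
    # tables read from disk
    n_metric <- if ("n_cells_metric" %in% names(t)) t$n_cells_metric
                else t$n_cells
    pool <- function(prefix) {
      .pooled_class_stats(t[[paste0("mean_", prefix)]],
                          t[[paste0("se_", prefix)]],
                          n_metric)
    }
    cc <- pool("curv_combined"); cp <- pool("curv_profile")
    cf <- pool("curv_planform")
    tibble::tibble(
      class_label = cl,
      mean_surface_complexity = if (length(sc)) mean(sc) else NA_real_,
      se_surface_complexity = .se(sc),
      percent_cover = if (cl %in% covers$class_label)
        covers$percent_cover[covers$class_label == cl] else NA_real_,
      mean_percent_slope = if (length(sl)) mean(sl) else NA_real_,
      se_percent_slope = .se(sl),
      mean_curv_combined = cc[["mean"]], se_curv_combined = cc[["se"]],
      mean_curv_profile = cp[["mean"]], se_curv_profile = cp[["se"]],
      mean_curv_planform = cf[["mean"]], se_curv_planform = cf[["se"]],
      n_features = nrow(t))
  })
  do.call(rbind, rows)
}

#' Aggregate cover totals across classes
#'
#' Sums per-class percent covers into the ecologically interesting totals:
#' overall biotic and abiotic cover, cover of the structurally complex
#' (plating + branching) morphotypes, and the dominant coral class.
#'
#' @param covers `tibble` with `class_label` and `percent_cover`.
#' @param taxonomy taxonomy `tibble` with `biotic` and `morphotype`.
#' @return A list: `total`, `biotic`, `abiotic`, `plating_branching`,
#'   `dominant_coral` (label), `dominant_coral_cover`.
#' @export
cover_totals <- function(covers, taxonomy) {
  m <- match(covers$class_label, taxonomy$class_label)
  if (anyNA(m))
    stop("cover class(es) not in taxonomy: ",
         paste(covers$class_label[is.na(m)], collapse = ", "))
  biotic <- taxonomy$biotic[m]
  morpho <- taxonomy$morphotype[m]
  pc <- covers$percent_cover
  coral <- which(biotic)
  dom <- coral[which.max(pc[coral])]
  list(
    total = sum(pc),
    biotic = sum(pc[biotic]),
    abiotic = sum(pc[!biotic]),
    plating_branching = sum(pc[morpho %in% c("plating", "branching")]),
    dominant_coral = covers$class_label[dom],
    dominant_coral_cover = pc[dom])
}

#' Full per-feature structural metrics table
#'
#' Runs the whole per-feature pipeline: surface complexity
#' ([surface_complexity_table()]), then zonal mean/SE of percent slope and
#' the three curvature rasters over the rasterized partition.
#'
#' @param grid an [elevation_grid()].
#' @param annotations an [annotation_set()].
#' @param z_unit_scale passed to [curvature_raster()].
#' @return A `tibble` with the full feature-table schema (see
#'   [write_feature_table()]).
#' @export
compute_feature_metrics <- function(grid, annotations, z_unit_scale = 1) {
  surf <- surface_complexity_table(grid, annotations)
  lab <- rasterize_partition(grid, annotations)
  slope <- feature_summary(lab, slope_raster(grid, units = "percent"))
  curv <- curvature_raster(grid, z_unit_scale = z_unit_scale)
  cc <- feature_summary(lab, curv$combined)
  cp <- feature_summary(lab, curv$profile)
  cf <- feature_summary(lab, curv$planform)
  stopifnot(identical(surf$feature_id, slope$feature_id))
  tibble::tibble(
    feature_id = surf$feature_id,
    class_label = surf$class_label,
    area_2d_m2 = surf$area_2d_m2,
    area_3d_m2 = surf$area_3d_m2,
    surface_complexity = surf$surface_complexity,
    n_cells = surf$n_cells,
    mean_percent_slope = slope$mean, se_percent_slope = slope$se,
    mean_curv_combined = cc$mean, se_curv_combined = cc$se,
    mean_curv_profile = cp$mean, se_curv_profile = cp$se,
    mean_curv_planform = cf$mean, se_curv_planform = cf$se,
    n_cells_metric = cc$n_cells)
}
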