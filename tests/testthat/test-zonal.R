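tax2 <- taxonomy(c("sand", "rock/rubble"), biotic = c(FALSE, FALSE))

test_that("rasterization assigns each cell to exactly one feature", {
  g <- grid_from_fun(function(x, y) 0, 10, 10, L = 0.1)
  whole <- annotation_feature("all", "sand", reeftopo:::rect_ring(0, 0, 1, 1))
  lab <- rasterize_partition(g, annotation_set(list(whole), tax2,
                                               plot_extent = c(0, 0, 1, 1)))
  expect_true(all(lab$labels == 1L))

  # two abutting rectangles: a partition, no double assignment
  left <- annotation_feature("L", "sand", reeftopo:::rect_ring(0, 0, 0.5, 1))
  right <- annotation_feature("R", "rock/rubble", reeftopo:::rect_ring(0.5, 0, 1, 1))
  lab2 <- rasterize_partition(g, annotation_set(list(left, right), tax2,
                                                plot_extent = c(0, 0, 1, 1)))
  expect_true(all(lab2$labels %in% c(1L, 2L)))
  expect_equal(sum(lab2$labels == 1L), 50)
  expect_equal(sum(lab2$labels == 2L), 50)

  # overlap is an error naming both features and the cell
  big <- annotation_feature("B", "sand", reeftopo:::rect_ring(0, 0, 0.7, 1))
  expect_error(
    rasterize_partition(g, annotation_set(list(big, right), tax2,
                                          plot_extent = c(0, 0, 1, 1))),
    "'B'.*'R'|'R'.*'B'")

  # sub-cell polygon away from any centre captures nothing but is flagged
  dot <- annotation_feature("dot", "sand",
                            reeftopo:::rect_ring(0.51, 0.51, 0.54, 0.54))
  lab3 <- rasterize_partition(g, annotation_set(list(dot), tax2,
                                                plot_extent = c(0, 0, 1, 1)))
  expect_equal(lab3$flagged_features, "dot")
  expect_true(all(lab3$labels == 0L))
})

test_that("feature summaries match brute-force means and SEs", {
  g <- grid_from_fun(function(x, y) 0, 6, 6, L = 1)
  f1 <- annotation_feature("c7", "sand", reeftopo:::rect_ring(1, 1, 5, 3))
  f2 <- annotation_feature("mix", "rock/rubble", reeftopo:::rect_ring(1, 4, 4, 5))
  ann <- annotation_set(list(f1, f2), tax2, plot_extent = c(0, 0, 6, 6))
  lab <- rasterize_partition(g, ann)

  vals <- matrix(NA_real_, 6, 6)
  vals[lab$labels == 1L] <- 7
  vals[lab$labels == 2L] <- c(1, 2, 3)
  mr <- metric_raster(vals, "percent_slope", "percent", "test", 1, g$origin)
  s <- feature_summary(lab, mr)
  expect_equal(s$mean[s$feature_id == "c7"], 7)
  expect_equal(s$se[s$feature_id == "c7"], 0)
  expect_equal(s$mean[s$feature_id == "mix"], 2)
  expect_equal(s$se[s$feature_id == "mix"], 1 / sqrt(3))

  # brute-force oracle on random data, and order invariance
  set.seed(14)
  vals2 <- matrix(rnorm(36), 6, 6)
  mr2 <- metric_raster(vals2, "percent_slope", "percent", "test", 1, g$origin)
  s2 <- feature_summary(lab, mr2)
  for (i in 1:2) {
    v <- vals2[lab$labels == i]
    expect_equal(s2$mean[i], mean(v))
    expect_equal(s2$se[i], stats::sd(v) / sqrt(length(v)))
  }
  ann_rev <- annotation_set(list(f2, f1), tax2, plot_extent = c(0, 0, 6, 6))
  s_rev <- feature_summary(rasterize_partition(g, ann_rev), mr2)
  expect_equal(s_rev$mean[s_rev$feature_id == "mix"],
               s2$mean[s2$feature_id == "mix"])
})

test_that("single-cell features report a missing SE, not zero", {
  g <- grid_from_fun(function(x, y) 0, 5, 5, L = 1)
  one <- annotation_feature("one", "sand", reeftopo:::rect_ring(2.1, 2.1, 2.9, 2.9))
  ann <- annotation_set(list(one), tax2, plot_extent = c(0, 0, 5, 5))
  lab <- rasterize_partition(g, ann)
  mr <- metric_raster(matrix(1, 5, 5), "percent_slope", "percent", "t", 1,
                      g$origin)
  s <- feature_summary(lab, mr)
  expect_equal(s$n_cells, 1L)
  expect_true(is.na(s$se))
})

test_that("percent cover uses vector areas and sums to 100 on a partition", {
  whole <- annotation_feature("all", "sand", reeftopo:::rect_ring(0, 0, 2, 1))
  ann <- annotation_set(list(whole), tax2, plot_extent = c(0, 0, 2, 1))
  pc <- percent_cover(ann)
  expect_equal(pc$percent_cover[pc$class_label == "sand"], 100)
  expect_equal(pc$percent_cover[pc$class_label == "rock/rubble"], 0)

  halves <- annotation_set(list(
    annotation_feature("a", "sand", reeftopo:::rect_ring(0, 0, 1, 1)),
    annotation_feature("b", "rock/rubble", reeftopo:::rect_ring(1, 0, 2, 1))),
    tax2, plot_extent = c(0, 0, 2, 1))
  pc2 <- percent_cover(halves)
  expect_equal(sort(pc2$percent_cover), c(50, 50))
  expect_equal(sum(pc2$percent_cover), 100, tolerance = 1e-3)

  # features poking out of the plot are clipped, with a warning
  out <- annotation_set(list(
    annotation_feature("o", "sand", reeftopo:::rect_ring(-1, 0, 1, 1))),
    tax2, plot_extent = c(0, 0, 2, 1))
  expect_warning(pc3 <- percent_cover(out), "clipped")
  expect_equal(pc3$percent_cover[pc3$class_label == "sand"], 50)
})

test_that("rasterized class areas converge to vector covers as cells shrink", {
  tri <- annotation_feature("t", "sand",
                            cbind(c(0.13, 1.83, 0.41), c(0.11, 0.32, 0.87)))
  ann <- annotation_set(list(tri), tax2, plot_extent = c(0, 0, 2, 1))
  vec_frac <- planimetric_area(tri) / 2
  err <- vapply(c(0.05, 0.0125), function(L) {
    g <- grid_from_fun(function(x, y) 0, round(1 / L), round(2 / L), L = L)
    lab <- rasterize_partition(g, ann)
    abs(sum(lab$labels == 1L) * L^2 / 2 - vec_frac)
  }, 0)
  expect_lte(err[2], err[1])
  expect_lt(err[2] / vec_frac, 0.02)
})

test_that("community summary aggregates feature replicates and pools curvature cells", {
  tab <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    class_label = c("sand", "sand", "rock/rubble"),
    surface_complexity = c(1, 3, 2),
    mean_percent_slope = c(10, 20, 5),
    n_cells = c(2L, 3L, 4L),
    n_cells_metric = c(2L, 3L, 4L),
    mean_curv_combined = c(1, 2, 0), se_curv_combined = c(0.5, 0.2, 0.1),
    mean_curv_profile = c(-1, -2, 0), se_curv_profile = c(0.5, 0.2, 0.1),
    mean_curv_planform = c(0, 0, 0), se_curv_planform = c(0.1, 0.1, 0.1))
  covers <- tibble::tibble(class_label = c("sand", "rock/rubble"),
                           percent_cover = c(60, 40))
  cs <- community_summary(tab, covers, taxonomy = tax2)
  sand <- cs[cs$class_label == "sand", ]
  expect_equal(sand$mean_surface_complexity, 2)
  expect_equal(sand$se_surface_complexity, 1)  # sd sqrt(2) / sqrt(2)
  expect_equal(sand$n_features, 2L)

  # single-feature class: SE missing, not zero
  rr <- cs[cs$class_label == "rock/rubble", ]
  expect_true(is.na(rr$se_surface_complexity))

  # curvature pooling: reconstruct the cell-level mean/SE exactly from
  # synthetic cell sets built to have the declared (mean, se, n)
  set.seed(15)
  ca <- scale(rnorm(2))[, 1] * 0.5 * sqrt(2) + 1      # mean 1, se 0.5, n 2
  cb <- scale(rnorm(3))[, 1] * 0.2 * sqrt(3) + 2      # mean 2, se 0.2, n 3
  pooled <- c(ca, cb)
  expect_equal(sand$mean_curv_combined, mean(pooled), tolerance = 1e-10)
  expect_equal(sand$se_curv_combined,
               stats::sd(pooled) / sqrt(5), tolerance = 1e-10)
})

test_that("cover totals aggregate morphotype and biotic groups", {
  tax <- reef_taxonomy()
  covers <- tibble::tibble(
    class_label = tax$class_label,
    percent_cover = c(10, 5, 5, 20, 30, 10, 15, 5))
  tot <- cover_totals(covers, tax)
  expect_equal(tot$total, 100)
  expect_equal(tot$abiotic, 20)
  expect_equal(tot$biotic, 80)
  expect_equal(tot$plating_branching, 10 + 20 + 10)
  expect_equal(tot$dominant_coral, "P. lobata")
})
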