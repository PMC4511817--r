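test_that("GeoTIFF round trip preserves values, cell size and origin exactly", {
  # identity read of a small zero grid at 0.5-cm cells
  f <- withr::local_tempfile(fileext = ".tif")
  write_dem(elevation_grid(matrix(0, 3, 3), 0.005), f)
  g <- load_dem(f)
  expect_identical(g$values, matrix(0, 3, 3))
  expect_equal(g$cell_size, 0.005)

  # bit-for-bit round trip of random doubles, with offset origin and nodata
  set.seed(1)
  m <- matrix(rnorm(100), 10, 10)
  m[c(3, 57)] <- NA
  g0 <- elevation_grid(m, 0.01, origin = c(12.5, -3.25))
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_dem(g0, f2)
  g1 <- load_dem(f2)
  expect_identical(g1$values, g0$values)
  expect_identical(nodata_mask(g1), is.na(m))
  expect_equal(g1$origin, c(12.5, -3.25))
})

test_that("depth mode negates on load and is an involution", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_dem(elevation_grid(matrix(1.0, 3, 3), 0.005), f)
  g <- load_dem(f, depth_mode = TRUE)
  expect_identical(g$values, matrix(-1.0, 3, 3))
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_dem(g, f2)
  g2 <- load_dem(f2, depth_mode = TRUE)
  expect_identical(g2$values, matrix(1.0, 3, 3))
})

test_that("malformed rasters are rejected with informative messages", {
  f <- withr::local_tempfile(fileext = ".tif")
  reeftopo:::write_geotiff(matrix(0, 4, 4), f, cell_size = c(0.01, 0.02),
                           origin = c(0, 0))
  expect_error(load_dem(f), "0.01.*0.02")

  f2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), f2)  # 3-band RGB
  expect_error(load_dem(f2), "multi-band")
})

test_that("tiff package reads back this codec's float32 payload", {
  set.seed(2)
  m <- matrix(runif(48), 6, 8)
  f <- withr::local_tempfile(fileext = ".tif")
  reeftopo:::write_geotiff(m, f, cell_size = 0.01, origin = c(0, 0),
                           dtype = "float32")
  r <- tiff::readTIFF(f)
  expect_equal(dim(r), dim(m))
  expect_lt(max(abs(r - m)), 1e-6)  # float32 quantisation only
})

test_that("GeoJSON annotations load, split multipolygons, and reject unknown labels", {
  tax <- reef_taxonomy()
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(geojson_text(paste(
    square_feature_json("sand", 0, 0, id = "s1"),
    square_feature_json("P. lobata", 2, 0, id = "c1"), sep = ",")), f)
  ann <- load_annotations(f, tax)
  expect_length(ann$features, 2)
  biotic <- vapply(ann$features, reeftopo:::feature_biotic, TRUE, tax)
  expect_equal(sum(biotic), 1L)

  # multipolygon with 3 parts shares the label and preserves total area
  mp <- paste0(
    '{"type":"Feature","properties":{"class":"rock/rubble","feature_id":"r"},',
    '"geometry":{"type":"MultiPolygon","coordinates":[',
    '[[[0,0],[1,0],[1,1],[0,1],[0,0]]],',
    '[[[2,0],[3,0],[3,2],[2,2],[2,0]]],',
    '[[[4,0],[5,0],[5,1],[4,1],[4,0]]]]}}')
  f2 <- withr::local_tempfile(fileext = ".geojson")
  writeLines(geojson_text(mp), f2)
  ann2 <- load_annotations(f2, tax)
  expect_length(ann2$features, 3)
  expect_equal(unique(vapply(ann2$features, `[[`, "", "class_label")),
               "rock/rubble")
  expect_equal(vapply(ann2$features, `[[`, "", "feature_id"),
               c("r-1", "r-2", "r-3"))
  total <- sum(vapply(ann2$features,
                      function(x) reeftopo:::polygon_area(x$polygon), 0))
  expect_equal(total, 4)

  # unknown label names the offender and the taxonomy
  f3 <- withr::local_tempfile(fileext = ".geojson")
  writeLines(geojson_text(square_feature_json("A. cytherea", 0, 0)), f3)
  tax_small <- taxonomy("sand", biotic = FALSE)
  expect_error(load_annotations(f3, tax_small), "A. cytherea")
})

test_that("annotation round trip through GeoJSON preserves geometry", {
  tax <- reef_taxonomy()
  hole <- reeftopo:::rect_ring(0.4, 0.4, 0.6, 0.6)
  fe <- annotation_feature("h1", "P. lobata",
                           reeftopo:::rect_ring(0, 0, 1, 1),
                           holes = list(hole))
  ann <- annotation_set(list(fe), tax, plot_extent = c(0, 0, 1, 1))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, f)
  back <- load_annotations(f, tax, plot_extent = c(0, 0, 1, 1))
  expect_equal(reeftopo:::polygon_area(back$features[[1]]$polygon), 0.96)
  expect_equal(back$features[[1]]$feature_id, "h1")
})

test_that("feature table writes a fixed schema with missing as empty, and round trips", {
  empty <- tibble::tibble(feature_id = character(), class_label = character())
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(empty, f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_match(lines, "^feature_id,class_label,area_2d_m2,area_3d_m2,surface_complexity")

  one <- tibble::tibble(
    feature_id = "F1", class_label = "sand",
    area_2d_m2 = 1 / 3, area_3d_m2 = pi, surface_complexity = 3 * pi,
    n_cells = 5L, mean_percent_slope = 12.25, se_percent_slope = NA_real_,
    mean_curv_combined = -0.02, se_curv_combined = NA_real_,
    mean_curv_profile = NA_real_, se_curv_profile = NA_real_,
    mean_curv_planform = NA_real_, se_curv_planform = NA_real_)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(one, f2)
  expect_length(readLines(f2), 2)
  back <- read_feature_table(f2)
  expect_identical(back$area_2d_m2, 1 / 3)   # full precision, not rounded
  expect_identical(back$area_3d_m2, pi)
  # masked metric is an empty field, never "0"
  expect_true(is.na(back$se_percent_slope))
  expect_match(readLines(f2)[2], "12.25,,", fixed = TRUE)
})
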