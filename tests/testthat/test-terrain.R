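test_that("window coefficients are exact on flat, planar and quadratic surfaces", {
  flat <- elevation_grid(matrix(5, 3, 3), 1)
  qc <- fit_quadratic_window(flat, 2, 2)
  expect_equal(unlist(qc[c("D", "E", "F", "G", "H")]),
               c(D = 0, E = 0, F = 0, G = 0, H = 0))

  plane <- grid_from_fun(function(x, y) 0.3 * x, 3, 3, L = 1)
  qc <- fit_quadratic_window(plane, 2, 2)
  expect_equal(qc$G, 0.3)
  expect_equal(abs(qc$D) + abs(qc$E) + abs(qc$F) + abs(qc$H), 0)

  # paraboloid centred on the window centre
  g <- grid_from_fun(function(x, y) -0.01 * ((x - 1.5)^2 + (y - 1.5)^2),
                     3, 3, L = 1)
  qc <- fit_quadratic_window(g, 2, 2)
  expect_equal(qc$D, -0.01)
  expect_equal(qc$E, -0.01)
  expect_equal(abs(qc$F) + abs(qc$G) + abs(qc$H), 0)
})

test_that("window fit refuses masked neighbours and non-interior cells", {
  m <- matrix(1, 3, 3); m[1, 1] <- NA
  g <- elevation_grid(m, 1)
  expect_error(fit_quadratic_window(g, 2, 2), "incomplete window")
  expect_error(fit_quadratic_window(g, 1, 2), "interior")
})

test_that("window fit matches a direct nine-point interpolation oracle", {
  set.seed(3)
  for (rep in 1:20) {
    L <- stats::runif(1, 0.001, 2)
    w <- matrix(rnorm(9), 3, 3)
    g <- elevation_grid(w, L)
    mine <- fit_quadratic_window(g, 2, 2)
    oracle <- zt_fit_oracle(w, L)
    for (cf in c("D", "E", "F", "G", "H"))
      expect_equal(mine[[cf]], oracle[[cf]], tolerance = 1e-10)
  }
})

test_that("slope is zero on flat ground and exact on planes", {
  flat <- elevation_grid(matrix(2, 5, 5), 0.5)
  expect_true(all(slope_raster(flat, "percent")$values[2:4, 2:4] == 0))
  expect_true(all(slope_raster(flat, "degrees")$values[2:4, 2:4] == 0))

  plane <- grid_from_fun(function(x, y) x, 5, 6, L = 1)
  sp_ <- slope_raster(plane, "percent")
  expect_equal(unique(as.vector(sp_$values[2:4, 2:5])), 100)
  sd_ <- slope_raster(plane, "degrees")
  expect_equal(unique(as.vector(sd_$values[2:4, 2:5])), 45)

  # border is masked, never padded
  expect_true(all(is.na(sp_$values[1, ])))
  expect_true(all(is.na(sp_$values[, 1])))

  # random planes: exact at 1e-12 (property over seeds)
  set.seed(4)
  for (rep in 1:10) {
    a <- rnorm(1); b <- rnorm(1); L <- stats::runif(1, 0.01, 1)
    g <- grid_from_fun(function(x, y) a * x + b * y, 6, 7, L = L)
    s <- slope_raster(g, "percent")
    expect_equal(max(abs(s$values - 100 * sqrt(a^2 + b^2)), na.rm = TRUE), 0,
                 tolerance = 1e-9)
  }
})

test_that("the 8-point weighted difference reproduces a hand-computed window", {
  # all three rows (1, 2, 3): dz/dx = 1, dz/dy = 0 -> 100%
  g <- elevation_grid(matrix(rep(c(1, 2, 3), each = 3), 3, 3), 1)
  s <- slope_raster(g, "percent")
  expect_equal(s$values[2, 2], 100)
  expect_error(slope_raster(elevation_grid(matrix(0, 2, 2), 1)),
               "smaller than 3x3")
})

test_that("curvature vanishes on planes and matches closed forms on dome/bowl", {
  plane <- grid_from_fun(function(x, y) 0.7 * x - 0.2 * y + 3, 6, 6, L = 0.5)
  cv <- curvature_raster(plane)
  for (nm in names(cv))
    expect_equal(max(abs(cv[[nm]]$values), na.rm = TRUE), 0, tolerance = 1e-9)

  dome <- grid_from_fun(function(x, y) -0.01 * ((x - 3)^2 + (y - 3)^2),
                        6, 6, L = 1)
  bowl <- grid_from_fun(function(x, y) +0.01 * ((x - 3)^2 + (y - 3)^2),
                        6, 6, L = 1)
  cvd <- curvature_raster(dome)
  cvb <- curvature_raster(bowl)
  expect_equal(max(abs(cvd$combined$values - 4), na.rm = TRUE), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(cvb$combined$values + 4), na.rm = TRUE), 0,
               tolerance = 1e-10)
  # dome/bowl antisymmetry in all three outputs
  for (nm in names(cvd))
    expect_equal(cvd[[nm]]$values, -cvb[[nm]]$values)
  # dome: profile negative (convex along slope), planform positive
  off_centre <- cvd$profile$values[2, 3]
  expect_lt(off_centre, 0)
  expect_gt(cvd$planform$values[2, 3], 0)

  expect_error(curvature_raster(dome, z_unit_scale = 0), "positive")
  cv2 <- curvature_raster(dome, z_unit_scale = 200)
  expect_equal(cv2$combined$values, cvd$combined$values * 200)
})

test_that("curvature is exact on random quadratic surfaces", {
  set.seed(5)
  for (rep in 1:10) {
    cf <- rnorm(6, sd = 0.1)
    L <- stats::runif(1, 0.05, 0.5)
    f <- function(x, y) cf[1] * x^2 + cf[2] * y^2 + cf[3] * x * y +
      cf[4] * x + cf[5] * y + cf[6]
    g <- grid_from_fun(f, 7, 7, L = L)
    cv <- curvature_raster(g)
    # combined curvature of a quadratic is constant: -200 (a + b)
    vals <- stats::na.omit(as.vector(cv$combined$values))
    expect_equal(max(abs(vals - (-200 * (cf[1] + cf[2])))), 0,
                 tolerance = 1e-8)
    # halving the cell size leaves quadratic curvature unchanged
    g2 <- grid_from_fun(f, 13, 13, L = L / 2)
    vals2 <- stats::na.omit(as.vector(curvature_raster(g2)$combined$values))
    expect_equal(mean(vals2), mean(vals), tolerance = 1e-8)
  }
})

test_that("rotating the surface rotates slope and preserves combined curvature", {
  set.seed(6)
  m <- matrix(rnorm(144), 12, 12)
  g <- elevation_grid(m, 1)
  rot <- function(x) t(x)[, nrow(x):1]  # 90 degrees counter-clockwise
  gr <- elevation_grid(rot(m), 1)
  expect_equal(slope_raster(gr)$values, rot(slope_raster(g)$values))
  expect_equal(curvature_raster(gr)$combined$values,
               rot(curvature_raster(g)$combined$values))
})

test_that("scaling elevations scales slope tangent and curvature linearly", {
  set.seed(8)
  m <- matrix(rnorm(64), 8, 8)
  g1 <- elevation_grid(m, 0.5)
  g2 <- elevation_grid(2 * m, 0.5)
  expect_equal(slope_raster(g2)$values, 2 * slope_raster(g1)$values)
  expect_equal(curvature_raster(g2)$combined$values,
               2 * curvature_raster(g1)$combined$values)
})
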