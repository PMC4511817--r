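# Grid built by sampling f(x, y) at cell centres; origin at the top-left
# outer corner (0, nr * L) so cell centres sit at positive x, y in (0, nr*L).
grid_from_fun <- function(f, nr, nc, L = 1, origin = c(0, nr * L)) {
  x <- origin[1] + (seq_len(nc) - 0.5) * L
  y <- origin[2] - (seq_len(nr) - 0.5) * L
  z <- outer(y, x, function(yy, xx) rep_len(f(xx, yy), length(xx)))
  elevation_grid(z, L, origin)
}

# Independent oracle for the 3x3 window coefficients: exact interpolation of
# the nine points by the full partial-quartic basis, solved directly.
zt_fit_oracle <- function(w, L) {
  xy <- expand.grid(x = c(-L, 0, L), y = c(L, 0, -L))  # Z1..Z9 row-wise
  xy <- xy[order(-xy$y, xy$x), ]
  x <- xy$x; y <- xy$y
  A <- cbind(x^2 * y^2, x^2 * y, x * y^2, x^2, y^2, x * y, x, y, 1)
  coef <- unname(solve(A, as.vector(t(w))))
  list(D = coef[4], E = coef[5], F = coef[6], G = coef[7], H = coef[8])
}

# single-colony scene on a flat matrix, for drape-accuracy checks
single_colony_grid <- function(profile_fun, radius, cell_size,
                               pad = 1.2) {
  n <- ceiling(2 * pad * radius / cell_size)
  g <- grid_from_fun(function(x, y) {
    cx <- n * cell_size / 2; cy <- n * cell_size / 2
    profile_fun(sqrt((x - cx)^2 + (y - cy)^2), x - cx, y - cy)
  }, n, n, cell_size)
  centre <- n * cell_size / 2
  list(grid = g, centre = c(centre, centre))
}

geojson_text <- function(features_json) {
  paste0('{"type":"FeatureCollection","features":[', features_json, "]}")
}

square_feature_json <- function(label, x0, y0, s = 1, id = NULL) {
  ring <- sprintf("[[%g,%g],[%g,%g],[%g,%g],[%g,%g],[%g,%g]]",
                  x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s, x0, y0)
  props <- if (is.null(id)) sprintf('{"class":"%s"}', label)
           else sprintf('{"class":"%s","feature_id":"%s"}', label, id)
  sprintf('{"type":"Feature","properties":%s,"geometry":{"type":"Polygon","coordinates":[%s]}}',
          props, ring)
}
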