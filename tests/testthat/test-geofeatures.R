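# Buffer extraction: point counts, road lengths, land-use areas, raster
# sampling and the assembled predictor matrix.

test_that("point counts use an inclusive boundary and Euclidean distance", {
  pts <- geo_points(data.frame(
    x = c(100, 200, 400, 600, 1200), y = 0))
  expect_identical(buffer_point_count(pts, c(0, 0), 500), 3L)
  # point at exactly the radius is counted
  on_edge <- geo_points(data.frame(x = 500, y = 0))
  expect_identical(buffer_point_count(on_edge, c(0, 0), 500), 1L)
  empty <- geo_points(data.frame(x = numeric(0), y = numeric(0)))
  expect_identical(buffer_point_count(empty, c(0, 0), 500), 0L)
  expect_error(buffer_point_count(pts, c(0, 0), -1), "positive")
})

test_that("CRS mismatches are rejected", {
  pts <- geo_points(data.frame(x = 1, y = 1), crs = "EPSG:32650")
  center <- structure(c(0, 0), crs = "EPSG:4326")
  expect_error(buffer_point_count(pts, center, 100), "CRS mismatch")
})

test_that("road length inside a buffer matches chord geometry", {
  through <- geo_lines(list(list(
    xy = cbind(c(-50000, 50000), c(0, 0)), class = "primary_road")))
  expect_equal(buffer_line_length(through, c(0, 0), 300), 600, tolerance = 1e-9)
  inside <- geo_lines(list(list(
    xy = cbind(c(-100, 50), c(0, 0)), class = "secondary_road")))
  expect_equal(buffer_line_length(inside, c(0, 0), 300), 150)
  empty <- geo_lines(list())
  expect_identical(buffer_line_length(empty, c(0, 0), 300), 0)
})

test_that("polygon area inside a buffer: containment and disjointness", {
  big <- geo_polygons(list(list(
    xy = cbind(c(-1e5, 1e5, 1e5, -1e5), c(-1e5, -1e5, 1e5, 1e5)),
    class = "arable")))
  expect_equal(buffer_polygon_area(big, c(0, 0), 300), 282743.34,
               tolerance = 1e-3)
  expect_identical(buffer_polygon_area(big, c(5e5, 0), 300), 0)
})

test_that("polygon area agrees with a Monte-Carlo oracle", {
  sc <- random_scene(17)
  r <- 900
  set.seed(99)
  mc <- mc_disk_area(sc$polys[1:3], sc$center, r)
  layer <- geo_polygons(lapply(sc$polys[1:3], function(p)
    list(xy = p$xy, class = "arable")))
  got <- buffer_polygon_area(layer, sc$center, r)
  expect_equal(got, mc, tolerance = 0.01)
})

test_that("raster sampling is nearest-cell and guards the extent", {
  vals <- matrix(as.numeric(1:12), nrow = 3, ncol = 4)   # rows = y
  r <- geo_raster(vals, 0, 0, 100)
  expect_equal(raster_sample(r, data.frame(x = 50, y = 50)), vals[1, 1])
  expect_equal(raster_sample(r, data.frame(x = 350, y = 250)), vals[3, 4])
  const <- geo_raster(matrix(7, 5, 5), 0, 0, 10)
  expect_true(all(raster_sample(const,
                                data.frame(x = runif(20, 0, 50),
                                           y = runif(20, 0, 50))) == 7))
  expect_error(raster_sample(r, data.frame(station_id = "S9", x = 1e6, y = 0)),
               "S9")
})

test_that("gradient raster samples reproduce the generating function", {
  xs <- seq(50, 950, by = 100)
  vals <- outer(xs, xs, function(y, x) 2 * x + y)   # rows = y
  r <- geo_raster(vals, 0, 0, 100)
  pts <- data.frame(x = c(50, 250, 850), y = c(150, 50, 950))
  expect_equal(raster_sample(r, pts), 2 * pts$x + pts$y)
})

test_that("predictor matrix has the full deterministic schema", {
  city <- cached_tiny_city(1)
  targets <- city$stations[1:2, ]
  met <- generate_meteorology(city, "heating_working_0")
  mv <- krige_met(met, targets)
  X <- build_predictor_matrix(city$layers, targets, buffer_spec(), mv)
  expect_identical(ncol(X), 282L)
  expect_identical(colnames(X), predictor_names(buffer_spec()))
  expect_true(all(X[, 1:276] >= 0))
  meta <- attr(X, "meta")
  expect_identical(nrow(meta), 282L)
  expect_identical(meta$units[meta$name == "grassland_900"], "m2")
  # without met values the met columns are omitted
  X2 <- build_predictor_matrix(city$layers, targets, buffer_spec())
  expect_identical(ncol(X2), 278L)
})

test_that("buffered values are nondecreasing in the radius", {
  city <- cached_tiny_city(1)
  X <- build_predictor_matrix(city$layers, city$stations[1:5, ], buffer_spec())
  meta <- attr(X, "meta")
  for (b in unique(meta$base[!is.na(meta$radius_m)])) {
    cols <- meta$name[meta$base == b & !is.na(meta$radius_m)]
    vals <- as.matrix(X[, cols])
    expect_true(all(apply(vals, 1, function(v) all(diff(v) >= -1e-9))),
                info = b)
  }
})

test_that("a station far from all features has all-zero buffered columns", {
  ext <- c(0, 0, 100000, 100000)
  landuse <- geo_polygons(list(list(
    xy = cbind(c(0, 5000, 5000, 0), c(0, 0, 5000, 5000)), class = "arable")))
  roads <- geo_lines(list(list(xy = cbind(c(0, 5000), c(100, 100)),
                               class = "primary_road")))
  poi <- geo_points(data.frame(x = c(100, 200), y = c(100, 200),
                               category = "catering"))
  industry <- geo_points(data.frame(x = 300, y = 300))
  rast <- geo_raster(matrix(5, 100, 100), 0, 0, 1000)
  layers <- geo_layers(landuse, roads, poi, industry, rast, rast, ext)
  far <- data.frame(station_id = "far", x = 90000, y = 90000)
  X <- build_predictor_matrix(layers, far, buffer_spec())
  buffered <- X[, seq_len(276)]
  expect_true(all(buffered == 0))
  expect_equal(X$elevation, 5)
})

test_that("similarity scaling: counts invariant, lengths x2, areas x4", {
  pts <- data.frame(x = c(100, 300, 800), y = c(0, 50, -300))
  lines <- list(list(xy = cbind(c(-2000, 2000), c(100, 100)),
                     class = "primary_road"))
  poly <- list(list(xy = cbind(c(-400, 400, 400, -400),
                               c(-400, -400, 400, 400)), class = "arable"))
  center <- c(0, 0); r <- 500
  c1 <- buffer_point_count(geo_points(pts), center, r)
  l1 <- buffer_line_length(geo_lines(lines), center, r)
  a1 <- buffer_polygon_area(geo_polygons(poly), center, r)
  pts2 <- pts; pts2$x <- 2 * pts2$x; pts2$y <- 2 * pts2$y
  lines2 <- list(list(xy = 2 * lines[[1]]$xy, class = "primary_road"))
  poly2 <- list(list(xy = 2 * poly[[1]]$xy, class = "arable"))
  expect_identical(buffer_point_count(geo_points(pts2), center, 2 * r), c1)
  expect_equal(buffer_line_length(geo_lines(lines2), center, 2 * r), 2 * l1,
               tolerance = 1e-9)
  expect_equal(buffer_polygon_area(geo_polygons(poly2), center, 2 * r), 4 * a1,
               tolerance = 1e-6)
})

test_that("translation invariance of the extracted features", {
  pts <- data.frame(x = c(100, 300, 800), y = c(0, 50, -300))
  lines <- list(list(xy = cbind(c(-2000, 2000), c(100, 100)),
                     class = "primary_road"))
  poly <- list(list(xy = cbind(c(-400, 400, 400, -400),
                               c(-400, -400, 400, 400)), class = "arable"))
  d <- c(12345, -6789)
  center <- c(0, 0); r <- 700
  expect_identical(
    buffer_point_count(geo_points(pts), center, r),
    buffer_point_count(geo_points(data.frame(x = pts$x + d[1],
                                             y = pts$y + d[2])), center + d, r))
  expect_equal(
    buffer_line_length(geo_lines(lines), center, r),
    buffer_line_length(geo_lines(list(list(
      xy = sweep(lines[[1]]$xy, 2, d, "+"), class = "primary_road"))),
      center + d, r),
    tolerance = 1e-9)
  expect_equal(
    buffer_polygon_area(geo_polygons(poly), center, r),
    buffer_polygon_area(geo_polygons(list(list(
      xy = sweep(poly[[1]]$xy, 2, d, "+"), class = "arable"))), center + d, r),
    tolerance = 1e-6)
})
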