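# Regression mapping: grid construction, surface evaluation, kriged
# smoothing and station-level scoring.

test_that("grid construction follows the lower-left anchoring rule", {
  g <- make_grid(c(0, 0, 9000, 9000), 3000)
  expect_identical(nrow(g), 9L)
  expect_equal(sort(unique(g$x)), c(1500, 4500, 7500))
  g1 <- make_grid(c(0, 0, 2000, 2000), 3000)
  expect_identical(nrow(g1), 1L)
  # the single anchored cell center still lies inside the extent
  expect_true(g1$x > 0 && g1$x < 2000 && g1$y > 0 && g1$y < 2000)
  # extent smaller than half the spacing: midpoint fallback
  g0 <- make_grid(c(0, 0, 1000, 1000), 3000)
  expect_identical(nrow(g0), 1L)
  expect_equal(c(g0$x, g0$y), c(500, 500))
  big <- make_grid(c(0, 0, 100000, 100000), 3000)
  expect_true(all(big$x > 0 & big$x < 100000 & big$y > 0 & big$y < 100000))
  expect_error(make_grid(c(0, 0, 100, 100), -3), "positive")
  expect_error(make_grid(c(0, 0, 0, 100), 10), "degenerate")
})

intercept_only_model <- function(b0, n = 10) {
  set.seed(1)
  stepwise_regress(data.frame(a = rnorm(n)), rep(b0, n))
}

reference_model <- function(season, day_type, hour) {
  path <- system.file("extdata", "reference_models.csv", package = "pmlur")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$season == season & tab$day_type == day_type &
               tab$hour == hour, ]
  terms <- tab[tab$name != "(Intercept)", ]
  m <- list(intercept = tab$coefficient[tab$name == "(Intercept)"],
            terms = data.frame(name = terms$name,
                               coefficient = terms$coefficient,
                               t = terms$t, p = terms$sig, vif = terms$vif,
                               partial_r2 = terms$partial_r2,
                               stringsAsFactors = FALSE),
            r2 = NA, adjusted_r2 = NA, rmse = NA,
            n_obs = 35L, residual_sd = NA)
  class(m) <- "lur_model"
  m
}

test_that("an intercept-only model maps to a constant surface", {
  city <- cached_tiny_city(1)
  grid <- make_grid(city$layers$extent, 5000)
  m <- intercept_only_model(42)
  surf <- predict_surface(m, city$layers, grid)
  expect_true(all(surf$prediction == 42))
  expect_identical(attr(surf, "n_clamped"), 0L)
})

test_that("the published winter-midnight equation evaluates correctly", {
  m <- reference_model("heating", "working", 0)
  newd <- data.frame(relative_humidity = 60, sports_leisure_2500 = 100,
                     elevation = 50)
  expect_equal(predict(m, newd), 140.524, tolerance = 1e-9)
})

test_that("negative predictions are clamped to zero and counted", {
  city <- cached_tiny_city(1)
  grid <- make_grid(city$layers$extent, 5000)
  m <- intercept_only_model(5)
  m$intercept <- -3                     # force negatives
  surf <- predict_surface(m, city$layers, grid)
  expect_true(all(surf$prediction == 0))
  expect_identical(attr(surf, "n_clamped"), nrow(grid))
})

test_that("missing model terms are rejected by name", {
  city <- cached_tiny_city(1)
  grid <- make_grid(city$layers$extent, 5000)
  m <- reference_model("heating", "working", 0)
  expect_error(predict_surface(m, city$layers, grid),
               "relative_humidity")
})

test_that("constant grid predictions krige to a constant raster", {
  g <- make_grid(c(0, 0, 9000, 9000), 3000)
  gp <- data.frame(x = g$x, y = g$y, prediction = 33)
  out <- krige_surface(gp, c(0, 0, 9000, 9000), fine_resolution_m = 1000)
  expect_true(all(out$raster$values == 33))
})

test_that("zero-nugget kriged surface reproduces the grid predictions", {
  g <- make_grid(c(0, 0, 30000, 30000), 3000)
  gp <- data.frame(x = g$x, y = g$y,
                   prediction = 20 + g$x / 2000 + g$y / 3000)
  out <- krige_surface(gp, c(0, 0, 30000, 30000), fine_resolution_m = 3000,
                       force_zero_nugget = TRUE)
  # fine cells align with the grid, so cell centers are grid centers
  at_centers <- raster_sample(out$raster, g)
  expect_equal(at_centers, gp$prediction, tolerance = 1e-6)
})

test_that("a smooth gradient surface is recovered monotonically", {
  g <- make_grid(c(0, 0, 30000, 30000), 3000)
  gp <- data.frame(x = g$x, y = g$y, prediction = 10 + g$x / 1000)
  out <- krige_surface(gp, c(0, 0, 30000, 30000), fine_resolution_m = 1500)
  rast <- out$raster
  xc <- rast$xmin + (seq_len(rast$ncol) - 0.5) * rast$res
  truth <- 10 + xc / 1000
  row_mean <- colMeans(rast$values)
  expect_gt(cor(row_mean, truth, method = "spearman"), 0.99)
})

test_that("station relative error follows its definition", {
  expect_equal(station_relative_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(station_relative_error(rep(110, 5), rep(100, 5)), 10)
  expect_equal(station_relative_error(rep(100, 5), rep(110, 5)),
               100 * (100 - 110) / 110)
  expect_error(station_relative_error(1, 0), "zero observed mean")
})
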