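# Synthetic city generator: configuration guards, point-process behaviour,
# terrain, meteorological fields and the observation model.

test_that("degenerate configurations are rejected", {
  expect_error(city_config(extent = c(0, 0, 0, 100)), "degenerate extent")
  expect_error(city_config(n_stations = 5), ">= 12")
  expect_error(city_config(poi_mean_counts = c(catering = 10)), "missing categories")
})

test_that("zero POI intensity yields an empty category", {
  counts <- default_poi_mean_counts() / 50
  counts["catering"] <- 0
  city <- generate_city(tiny_city_config(seed = 3, poi_mean_counts = counts))
  expect_identical(sum(city$layers$poi$category == "catering"), 0L)
  expect_gt(sum(city$layers$poi$category == "shopping"), 0L)
})

test_that("per-category POI counts follow the configured Poisson mean", {
  n_seeds <- 20L
  counts <- sapply(seq_len(n_seeds), function(s) {
    city <- generate_city(tiny_city_config(seed = 100 + s))
    table(factor(city$layers$poi$category, levels = pmlur:::POI_CATEGORIES))
  })
  lambda <- round(default_poi_mean_counts() / 15)[pmlur:::POI_CATEGORIES]
  m <- rowMeans(counts)
  # mean over seeds within 3 standard errors of the Poisson mean
  expect_true(all(abs(m - lambda) <= 3 * sqrt(lambda / n_seeds) + 1e-9))
})

test_that("terrain gradient is high in the northwest, low in the southeast", {
  city <- cached_tiny_city(1)
  ele <- city$layers$elevation
  mid_r <- ele$nrow %/% 2; mid_c <- ele$ncol %/% 2
  nw <- mean(ele$values[(mid_r + 1):ele$nrow, 1:mid_c])        # high y, low x
  se <- mean(ele$values[1:mid_r, (mid_c + 1):ele$ncol])        # low y, high x
  expect_gt(nw, se)
})

test_that("city generation is seeded and bit-reproducible", {
  a <- generate_city(tiny_city_config(seed = 9))
  b <- generate_city(tiny_city_config(seed = 9))
  expect_identical(a$stations, b$stations)
  expect_identical(a$layers$poi, b$layers$poi)
  expect_identical(a$layers$elevation$values, b$layers$elevation$values)
  c2 <- generate_city(tiny_city_config(seed = 10))
  expect_false(identical(a$layers$poi, c2$layers$poi))
})

test_that("meteorology: zero sill returns the exact slot mean everywhere", {
  city <- cached_tiny_city(1)
  cfg <- pmlur:::default_met_config()
  for (v in pmlur:::MET_VARIABLES) cfg[[v]]$sill <- 0
  met <- generate_meteorology(city, "heating_working_0", seed = 5,
                              met_config = cfg)
  expected_rh <- cfg$relative_humidity$base[["heating"]] +
    cfg$relative_humidity$hour[["0"]]
  expect_true(all(met$relative_humidity == expected_rh))
})

test_that("meteorology is reproducible and rejects a bad covariance range", {
  city <- cached_tiny_city(1)
  a <- generate_meteorology(city, "non_heating_working_8", seed = 11)
  b <- generate_meteorology(city, "non_heating_working_8", seed = 11)
  expect_identical(a, b)
  cfg <- pmlur:::default_met_config()
  cfg$temperature$range_m <- -5
  expect_error(generate_meteorology(city, "heating_working_0", seed = 1,
                                    met_config = cfg), "range must be positive")
})

test_that("met field correlation decays with distance", {
  city <- generate_city(tiny_city_config(seed = 2, n_met_stations = 120L))
  met <- generate_meteorology(city, "heating_working_0", seed = 21)
  emp <- empirical_variogram(data.frame(x = met$x, y = met$y,
                                        value = met$temperature),
                             n_bins = 5L)
  # semivariance grows from the nearest to the farthest bin
  expect_lt(emp$gamma[1], emp$gamma[nrow(emp)])
})

test_that("noiseless observations equal the true linear predictor", {
  city <- cached_tiny_city(1)
  truth <- synthetic_truth(list(heating_working_0 = list(
    intercept = 40, coefficients = c(elevation = -0.05, catering_900 = 0.5),
    noise_sd = 0)))
  obs <- generate_observations(city, truth, "heating_working_0",
                               seed = 7, missing_rate = 0)
  X <- truth_design_matrix(city, truth, "heating_working_0")
  lin <- 40 + as.matrix(X) %*% c(-0.05, 0.5)
  expect_equal(obs$pm25, as.numeric(lin), tolerance = 1e-12)
  expect_false(any(obs$missing))
})

test_that("missing-value convention: floor(rate * n) stations removed", {
  city <- generate_city(tiny_city_config(seed = 4, n_stations = 35L))
  truth <- default_truth()
  obs <- generate_observations(city, truth, "heating_working_0",
                               seed = 3, missing_rate = 0.1)
  expect_identical(sum(!is.na(obs$pm25)), 32L)
  expect_identical(sum(obs$missing), 3L)
})

test_that("unknown truth variables are rejected by name", {
  expect_error(synthetic_truth(list(heating_working_0 = list(
    intercept = 0, coefficients = c(bogus_9999 = 1), noise_sd = 1))),
    "bogus_9999")
})

test_that("refit residual SD on the true support brackets the noise SD", {
  city <- generate_city(tiny_city_config(seed = 6, n_stations = 200L))
  truth <- synthetic_truth(list(heating_working_0 = list(
    intercept = 30, coefficients = c(elevation = -0.06, catering_900 = 0.6),
    noise_sd = 5)))
  obs <- generate_observations(city, truth, "heating_working_0",
                               seed = 13, missing_rate = 0)
  X <- truth_design_matrix(city, truth, "heating_working_0")
  fit <- lm(obs$pm25 ~ ., data = X)
  expect_gt(summary(fit)$sigma, 4)
  expect_lt(summary(fit)$sigma, 6)
})

test_that("truth design matrix matches the predictor-matrix columns", {
  city <- cached_tiny_city(1)
  truth <- synthetic_truth(list(heating_working_0 = list(
    intercept = 0, coefficients = c(catering_900 = 1, woodland_1300 = 1,
                                    relative_humidity = 1, elevation = 1),
    noise_sd = 1)))
  slot_id <- "heating_working_0"
  X <- truth_design_matrix(city, truth, slot_id)
  met <- generate_meteorology(city, slot_id)
  mv <- krige_met(met, city$stations)
  full <- build_predictor_matrix(city$layers, city$stations, buffer_spec(), mv)
  for (v in colnames(X)) expect_equal(X[[v]], full[[v]], tolerance = 1e-12)
})

test_that("empty truth support yields a zero-column design matrix", {
  city <- cached_tiny_city(1)
  truth <- synthetic_truth(list(heating_working_0 = list(
    intercept = 5, coefficients = numeric(0), noise_sd = 0)))
  X <- truth_design_matrix(city, truth, "heating_working_0")
  expect_identical(ncol(X), 0L)
  expect_identical(nrow(X), nrow(city$stations))
})
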