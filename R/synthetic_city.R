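# Synthetic study area with known statistical structure: a planar "city"
# (POI point processes, ring+radial roads, Voronoi land-use mosaic, NW-high
# terrain, center-decaying population), correlated meteorological fields,
# and station observations drawn from a known sparse linear model.

# --- seeded substreams ------------------------------------------------------
# One global seed per run, split into named substreams so that adding a
# stage never shifts another stage's draws. The derived seed stays < 2^31.
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- configuration ----------------------------------------------------------

default_poi_mean_counts <- function() {
  c(catering = 12000, scenic_spots = 1500, public_facilities = 5000,
    companies = 11000, shopping = 9000, transportation = 6000,
    financial_banks = 4000, science_education = 5000,
    residential_housing = 15000, life_services = 10000,
    sports_leisure = 3000, medical_care = 3500, government = 2500)
}

#' Synthetic city configuration
#'
#' Defines the study-area conditions the generator emulates: a 100 km x
#' 100 km planar extent, 35 PM2.5 monitoring stations (clustered towards the
#' urban core, as real networks are), 33 meteorological stations,
#' center-decaying inhomogeneous Poisson POI processes, a ring-and-radial
#' road skeleton, a Voronoi land-use mosaic, a terrain gradient that is high
#' in the northwest and low in the southeast, and a population surface
#' decaying from the center.
#'
#' @param extent numeric c(xmin, ymin, xmax, ymax) in metres.
#' @param n_stations number of monitoring stations (>= 12 so a 10-fold CV
#'   always has enough data).
#' @param n_met_stations number of meteorological stations.
#' @param poi_mean_counts named vector of expected POI counts per category.
#' @param poi_decay_m length scale of the exp(-d/lambda) intensity decay
#'   from the city center, metres (per-category vector or scalar).
#' @param n_industry expected industrial point-source count.
#' @param road_spec list(n_rings, n_radials, n_secondary).
#' @param landuse_seeds_per_class Voronoi mosaic seeds per land-use class.
#' @param terrain_spec list(direction = unit-ish vector pointing uphill,
#'   amplitude_m, base_m).
#' @param elevation_res_m,population_res_m raster cell sizes (metres).
#' @param rng_seed integer seed for all city-construction randomness.
#' @return object of class `city_config`.
#' @export
city_config <- function(extent = c(0, 0, 100000, 100000),
                        n_stations = 35L,
                        n_met_stations = 33L,
                        poi_mean_counts = default_poi_mean_counts(),
                        poi_decay_m = 15000,
                        n_industry = 2000L,
                        road_spec = list(n_rings = 5L, n_radials = 8L,
                                         n_secondary = 300L),
                        landuse_seeds_per_class = 8L,
                        terrain_spec = list(direction = c(-1, 1),
                                            amplitude_m = 600,
                                            base_m = 40),
                        elevation_res_m = 1000,
                        population_res_m = 1000,
                        rng_seed = 1L) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("degenerate extent: need xmin < xmax and ymin < ymax")
  }
  if (n_stations < 12L) stop("n_stations must be >= 12 to survive 10-fold CV")
  if (n_met_stations < 3L) stop("n_met_stations must be >= 3")
  miss <- setdiff(POI_CATEGORIES, names(poi_mean_counts))
  if (length(miss)) stop("poi_mean_counts missing categories: ",
                         paste(miss, collapse = ", "))
  if (any(poi_mean_counts < 0) || n_industry < 0) stop("counts must be >= 0")
  structure(list(extent = extent, n_stations = as.integer(n_stations),
                 n_met_stations = as.integer(n_met_stations),
                 poi_mean_counts = poi_mean_counts,
                 poi_decay_m = poi_decay_m, n_industry = as.integer(n_industry),
                 road_spec = road_spec,
                 landuse_seeds_per_class = as.integer(landuse_seeds_per_class),
                 terrain_spec = terrain_spec,
                 elevation_res_m = elevation_res_m,
                 population_res_m = population_res_m,
                 rng_seed = as.integer(rng_seed)),
            class = "city_config")
}

# sample n points with intensity proportional to exp(-d_center/lambda)
# by rejection from the uniform distribution on the extent
sample_center_decay <- function(n, extent, lambda, center) {
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  xs <- numeric(n); ys <- numeric(n); got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 100L)
    x <- runif(m, extent[1], extent[3])
    y <- runif(m, extent[2], extent[4])
    d <- sqrt((x - center[1])^2 + (y - center[2])^2)
    keep <- runif(m) < exp(-d / lambda)
    k <- min(sum(keep), n - got)
    if (k > 0L) {
      xs[(got + 1L):(got + k)] <- x[keep][seq_len(k)]
      ys[(got + 1L):(got + k)] <- y[keep][seq_len(k)]
      got <- got + k
    }
  }
  cbind(xs, ys)
}

# --- city generation --------------------------------------------------------

#' Generate the synthetic study area
#'
#' All construction randomness flows from `config$rng_seed` through named
#' substreams, so repeated calls are bit-reproducible and meteorology or
#' observation draws never shift the city itself.
#'
#' @param config a [city_config()].
#' @return list of class `synthetic_city` with elements `layers`
#'   ([geo_layers()]), `stations` and `met_stations` (data frames with
#'   station_id, x, y), and the `config`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  ext <- config$extent
  center <- c((ext[1] + ext[3]) / 2, (ext[2] + ext[4]) / 2)
  W <- ext[3] - ext[1]; H <- ext[4] - ext[2]
  crs <- "synthetic:meters"

  stations <- with_seed(substream_seed(config$rng_seed, "city/stations"), {
    n <- config$n_stations
    n_core <- round(0.6 * n)
    sx <- c(rnorm(n_core, center[1], W / 8), runif(n - n_core, ext[1], ext[3]))
    sy <- c(rnorm(n_core, center[2], H / 8), runif(n - n_core, ext[2], ext[4]))
    sx <- pmin(pmax(sx, ext[1] + W * 0.01), ext[3] - W * 0.01)
    sy <- pmin(pmax(sy, ext[2] + H * 0.01), ext[4] - H * 0.01)
    data.frame(station_id = sprintf("S%03d", seq_len(n)), x = sx, y = sy,
               stringsAsFactors = FALSE)
  })

  met_stations <- with_seed(substream_seed(config$rng_seed, "city/met_stations"), {
    n <- config$n_met_stations
    data.frame(station_id = sprintf("M%03d", seq_len(n)),
               x = runif(n, ext[1], ext[3]), y = runif(n, ext[2], ext[4]),
               stringsAsFactors = FALSE)
  })

  lambda <- rep(config$poi_decay_m, length.out = length(POI_CATEGORIES))
  names(lambda) <- POI_CATEGORIES
  poi <- with_seed(substream_seed(config$rng_seed, "city/poi"), {
    parts <- lapply(POI_CATEGORIES, function(cat) {
      n <- rpois(1L, config$poi_mean_counts[[cat]])
      xy <- sample_center_decay(n, ext, lambda[[cat]], center)
      if (n == 0L) {
        data.frame(x = numeric(0), y = numeric(0), category = character(0),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(x = xy[, 1], y = xy[, 2], category = cat,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, parts)
  })

  industry <- with_seed(substream_seed(config$rng_seed, "city/industry"), {
    n <- rpois(1L, config$n_industry)
    xy <- sample_center_decay(n, ext, mean(lambda) * 1.5, center)
    data.frame(x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  })

  roads <- with_seed(substream_seed(config$rng_seed, "city/roads"), {
    rs <- config$road_spec
    lines <- list()
    rmax <- 0.45 * min(W, H)
    if (rs$n_rings > 0) {
      radii <- rmax * seq_len(rs$n_rings) / rs$n_rings
      for (r in radii) {
        th <- seq(0, 2 * pi, length.out = 65L) + runif(1, 0, 2 * pi / 64)
        lines[[length(lines) + 1L]] <-
          list(xy = cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
               class = "primary_road")
      }
    }
    if (rs$n_radials > 0) {
      th0 <- runif(1, 0, 2 * pi / rs$n_radials)
      for (k in seq_len(rs$n_radials)) {
        th <- th0 + 2 * pi * (k - 1) / rs$n_radials + rnorm(1, 0, 0.03)
        lines[[length(lines) + 1L]] <-
          list(xy = rbind(center,
                          center + rmax * 1.1 * c(cos(th), sin(th))),
               class = "primary_road")
      }
    }
    if (rs$n_secondary > 0) {
      mid <- sample_center_decay(rs$n_secondary, ext, mean(lambda), center)
      len <- runif(rs$n_secondary, 1000, 3000)
      ang <- runif(rs$n_secondary, 0, pi)
      for (k in seq_len(rs$n_secondary)) {
        d <- len[k] / 2 * c(cos(ang[k]), sin(ang[k]))
        lines[[length(lines) + 1L]] <-
          list(xy = rbind(mid[k, ] - d, mid[k, ] + d), class = "secondary_road")
      }
    }
    lines
  })

  landuse <- with_seed(substream_seed(config$rng_seed, "city/landuse"), {
    nps <- config$landuse_seeds_per_class
    seeds <- NULL; classes <- character(0)
    for (cl in LANDUSE_CLASSES) {
      # urban classes cluster towards the center; open classes are uniform
      if (cl %in% c("commercial_service", "residential", "industrial_mining")) {
        sx <- rnorm(nps, center[1], W / 6); sy <- rnorm(nps, center[2], H / 6)
        sx <- pmin(pmax(sx, ext[1]), ext[3]); sy <- pmin(pmax(sy, ext[2]), ext[4])
      } else {
        sx <- runif(nps, ext[1], ext[3]); sy <- runif(nps, ext[2], ext[4])
      }
      seeds <- rbind(seeds, cbind(sx, sy))
      classes <- c(classes, rep(cl, nps))
    }
    cells <- voronoi_cells(seeds, ext)
    keep <- vapply(cells, function(p) nrow(p) >= 3L, TRUE)
    mapply(function(p, cl) list(xy = p, class = cl, convex = TRUE),
           cells[keep], classes[keep], SIMPLIFY = FALSE)
  })

  elev <- with_seed(substream_seed(config$rng_seed, "city/elevation"), {
    ts <- config$terrain_spec
    dir <- ts$direction / sqrt(sum(ts$direction^2))
    res <- config$elevation_res_m
    nc <- ceiling(W / res); nr <- ceiling(H / res)
    xc <- ext[1] + (seq_len(nc) - 0.5) * res
    yc <- ext[2] + (seq_len(nr) - 0.5) * res
    u <- outer(yc - center[2], xc - center[1],
               function(dy, dx) (dx * dir[1] + dy * dir[2]))
    u <- (u - min(u)) / max(max(u) - min(u), 1)
    vals <- ts$base_m + ts$amplitude_m * u
    # smooth large-scale bumps
    nb <- 10L
    bx <- runif(nb, ext[1], ext[3]); by <- runif(nb, ext[2], ext[4])
    ba <- rnorm(nb, 0, ts$amplitude_m * 0.03); bs <- min(W, H) / 10
    for (k in seq_len(nb)) {
      vals <- vals + ba[k] * outer(yc, xc, function(y, x)
        exp(-((x - bx[k])^2 + (y - by[k])^2) / (2 * bs^2)))
    }
    geo_raster(vals, ext[1], ext[2], res)
  })

  pop <- with_seed(substream_seed(config$rng_seed, "city/population"), {
    res <- config$population_res_m
    nc <- ceiling(W / res); nr <- ceiling(H / res)
    xc <- ext[1] + (seq_len(nc) - 0.5) * res
    yc <- ext[2] + (seq_len(nr) - 0.5) * res
    d <- outer(yc, xc, function(y, x)
      sqrt((x - center[1])^2 + (y - center[2])^2))
    vals <- 8000 * exp(-d / 12000) * exp(matrix(rnorm(nr * nc, 0, 0.3), nr, nc))
    geo_raster(vals, ext[1], ext[2], res)
  })

  layers <- geo_layers(landuse = geo_polygons(landuse, crs),
                       roads = geo_lines(roads, crs),
                       poi = geo_points(poi, crs),
                       industry = geo_points(industry, crs),
                       elevation = elev, population = pop,
                       extent = ext, crs = crs)
  structure(list(layers = layers, stations = stations,
                 met_stations = met_stations, config = config),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("<synthetic_city> seed", x$config$rng_seed, "\n")
  cat("  monitoring stations:", nrow(x$stations),
      "| met stations:", nrow(x$met_stations), "\n")
  print(x$layers)
  invisible(x)
}

# --- meteorology ------------------------------------------------------------

default_met_config <- function() {
  list(
    # slot means: season base + hour offset; sill/range of the spatial field
    temperature = list(base = c(heating = -2, non_heating = 26),
                       hour = c("0" = -2, "8" = 0, "18" = 1),
                       sill = 2.25, range_m = 30000),
    relative_humidity = list(base = c(heating = 60, non_heating = 52),
                             hour = c("0" = 5, "8" = 0, "18" = -3),
                             sill = 64, range_m = 30000),
    pressure = list(base = c(heating = 1021, non_heating = 1006),
                    hour = c("0" = 0, "8" = 1, "18" = -1),
                    sill = 1, range_m = 40000),
    wind_speed = list(base = c(heating = 2.4, non_heating = 2.0),
                      hour = c("0" = -0.3, "8" = 0, "18" = 0.2),
                      sill = 0.25, range_m = 25000)
  )
}

slot_met_mean <- function(met_config, var, slot) {
  cfg <- met_config[[var]]
  unname(cfg$base[[slot$season]] + cfg$hour[[as.character(slot$hour)]])
}

# Gaussian random field with exponential covariance sill*exp(-d/range)
# realised at given coordinates (Cholesky of the covariance matrix).
grf_exponential <- function(xy, sill, range_m, mean_value = 0) {
  n <- nrow(xy)
  if (range_m <= 0) stop("covariance range must be positive")
  if (sill < 0) stop("sill must be >= 0")
  if (sill == 0) return(rep(mean_value, n))
  d <- as.matrix(stats::dist(xy))
  C <- sill * exp(-d / range_m)
  L <- chol(C + diag(1e-8 * sill, n))
  as.numeric(mean_value + crossprod(L, stats::rnorm(n)))
}

#' Generate meteorological station values for one slot
#'
#' Each variable (temperature degC, relative humidity %, pressure hPa, wind
#' speed m/s) is drawn from a Gaussian random field with exponential
#' covariance around a slot-specific mean (season base + hour offset).
#' Humidity is clipped to [0, 100] and wind speed to >= 0.
#'
#' @param city a `synthetic_city`.
#' @param slot a [slot()] or slot id string.
#' @param seed integer; default derives a canonical per-slot seed from the
#'   city's `rng_seed`, so the same slot always sees the same weather.
#' @param met_config per-variable list(base, hour, sill, range_m).
#' @return data frame: station_id, x, y and the four met variables.
#' @export
generate_meteorology <- function(city, slot, seed = NULL,
                                 met_config = default_met_config()) {
  slot <- as_slot(slot)
  if (is.null(seed)) {
    seed <- substream_seed(city$config$rng_seed, paste0("met/", slot$slot_id))
  }
  ms <- city$met_stations
  if (nrow(ms) == 0L) stop("city has no met stations")
  xy <- as.matrix(ms[, c("x", "y")])
  out <- ms
  with_seed(seed, {
    for (v in MET_VARIABLES) {
      cfg <- met_config[[v]]
      vals <- grf_exponential(xy, cfg$sill, cfg$range_m,
                              slot_met_mean(met_config, v, slot))
      if (v == "relative_humidity") vals <- pmin(pmax(vals, 0), 100)
      if (v == "wind_speed") vals <- pmax(vals, 0)
      out[[v]] <- vals
    }
  })
  out
}

# --- ground truth and observations ------------------------------------------

#' Ground-truth sparse linear model per slot
#'
#' @param slots named list: slot id -> list(intercept, coefficients (named
#'   numeric over predictor-matrix column names), noise_sd).
#' @param spec the [buffer_spec()] whose schema the variable names must
#'   belong to.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(slots, spec = buffer_spec()) {
  schema <- predictor_names(spec)
  for (id in names(slots)) {
    s <- slots[[id]]
    bad <- setdiff(names(s$coefficients), schema)
    if (length(bad)) {
      stop("truth for slot '", id, "' names unknown variables: ",
           paste(bad, collapse = ", "))
    }
    if (length(s$coefficients) > 6L) {
      stop("truth support for slot '", id, "' exceeds 6 variables")
    }
    if (is.null(s$noise_sd) || s$noise_sd < 0) {
      stop("truth for slot '", id, "' needs noise_sd >= 0")
    }
  }
  structure(list(slots = slots, spec = spec), class = "synthetic_truth")
}

#' Default ground truth for the 12 slots
#'
#' Heating-season slots are humidity-dominated with an elevation decrease
#' (pollution accumulates in the low southeast plain) and a POI term;
#' non-heating slots are POI/road dominated with a temperature term, echoing
#' the seasonal contrast reported for hourly LUR models. Noise SDs are of
#' the order of 10 ug/m3 in winter and 4 ug/m3 in summer.
#'
#' @param spec a [buffer_spec()].
#' @return a [synthetic_truth()].
#' @export
default_truth <- function(spec = buffer_spec()) {
  s <- list(
    heating_working_0 = list(intercept = 25, coefficients = c(
      relative_humidity = 1.6, sports_leisure_2500 = 0.9, elevation = -0.08),
      noise_sd = 12),
    heating_working_8 = list(intercept = 20, coefficients = c(
      relative_humidity = 1.2, primary_road_1500 = 0.002, elevation = -0.06),
      noise_sd = 12),
    heating_working_18 = list(intercept = 130, coefficients = c(
      relative_humidity = 1.7, temperature = 2.2, shopping_2500 = 0.25),
      noise_sd = 14),
    heating_non_working_0 = list(intercept = 45, coefficients = c(
      relative_humidity = 1.4, shopping_2500 = 0.35, elevation = -0.07),
      noise_sd = 13),
    heating_non_working_8 = list(intercept = 40, coefficients = c(
      relative_humidity = 1.1, catering_900 = 0.8, grassland_800 = -2e-6),
      noise_sd = 11),
    heating_non_working_18 = list(intercept = 90, coefficients = c(
      relative_humidity = 2.0, shopping_3000 = 0.2, elevation = -0.05),
      noise_sd = 15),
    non_heating_working_0 = list(intercept = 12, coefficients = c(
      temperature = 0.8, residential_housing_500 = 0.45, grassland_3000 = -1.5e-7),
      noise_sd = 4),
    non_heating_working_8 = list(intercept = 30, coefficients = c(
      secondary_road_300 = 0.004, financial_banks_3000 = -0.01,
      life_services_300 = 0.5), noise_sd = 4.5),
    non_heating_working_18 = list(intercept = 32, coefficients = c(
      residential_housing_300 = 0.7, scenic_spots_3000 = 0.05), noise_sd = 4),
    non_heating_non_working_0 = list(intercept = 18, coefficients = c(
      residential_housing_2500 = 0.012, temperature = 0.5), noise_sd = 3.5),
    non_heating_non_working_8 = list(intercept = 20, coefficients = c(
      medical_care_300 = 1.0, public_facilities_2000 = 0.05,
      relative_humidity = 0.15), noise_sd = 4.5),
    non_heating_non_working_18 = list(intercept = 16, coefficients = c(
      science_education_500 = 0.3, primary_road_2500 = 5e-5), noise_sd = 4)
  )
  synthetic_truth(s, spec)
}

truth_for_slot <- function(truth, slot) {
  slot <- as_slot(slot)
  s <- truth$slots[[slot$slot_id]]
  if (is.null(s)) stop("truth has no entry for slot '", slot$slot_id, "'")
  s
}

#' True-support design matrix at the monitoring stations
#'
#' Returns, for the truth's support variables, exactly the values the
#' predictor-extraction stage would compute for those columns (buffered
#' features from the layers; meteorological covariates as the kriged-to-
#' station values the pipeline itself uses as predictors).
#'
#' @param city a `synthetic_city`.
#' @param truth a [synthetic_truth()].
#' @param slot slot or slot id.
#' @param met optional precomputed met-station table from
#'   [generate_meteorology()]; defaults to the canonical per-slot weather.
#' @return data frame with one column per support variable, rows aligned
#'   with `city$stations`.
#' @export
truth_design_matrix <- function(city, truth, slot, met = NULL) {
  slot <- as_slot(slot)
  st <- truth_for_slot(truth, slot)
  vars <- names(st$coefficients)
  targets <- city$stations
  out <- as.data.frame(matrix(numeric(0), nrow = nrow(targets), ncol = 0))
  if (length(vars) == 0L) {
    rownames(out) <- targets$station_id
    return(out)
  }
  met_vars <- intersect(vars, MET_VARIABLES)
  met_values <- NULL
  if (length(met_vars)) {
    if (is.null(met)) met <- generate_meteorology(city, slot)
    met_values <- krige_met(met, targets)
  }
  X <- extract_variables(city$layers, targets, vars, met_values)
  rownames(X) <- targets$station_id
  X
}

#' Simulate per-slot station observations
#'
#' y_i = intercept + sum_j beta_j x_ij + eps_i with eps ~ N(0, noise_sd^2).
#' A fraction `missing_rate` of stations is marked missing (value NA);
#' negative draws are floored at 0.1 ug/m3 and flagged.
#'
#' @param city a `synthetic_city`.
#' @param truth a [synthetic_truth()].
#' @param slot slot or slot id.
#' @param seed integer seed for the noise and missingness draws; default
#'   derives a per-slot substream from the city seed.
#' @param missing_rate fraction of stations marked missing
#'   (n_missing = floor(missing_rate * n)).
#' @return data frame of class `observation_set`: station_id, x, y, season,
#'   day_type, hour, pm25, missing, floored.
#' @export
generate_observations <- function(city, truth, slot, seed = NULL,
                                  missing_rate = 0) {
  slot <- as_slot(slot)
  if (is.null(seed)) {
    seed <- substream_seed(city$config$rng_seed, paste0("obs/", slot$slot_id))
  }
  st <- truth_for_slot(truth, slot)
  X <- truth_design_matrix(city, truth, slot)
  lin <- st$intercept + if (ncol(X)) {
    as.numeric(as.matrix(X) %*% st$coefficients[colnames(X)])
  } else 0
  n <- nrow(city$stations)
  with_seed(seed, {
    y <- lin + stats::rnorm(n, 0, st$noise_sd)
    floored <- y < 0
    y[floored] <- 0.1
    n_missing <- floor(missing_rate * n)
    missing <- rep(FALSE, n)
    if (n_missing > 0L) missing[sample.int(n, n_missing)] <- TRUE
    y[missing] <- NA_real_
    out <- data.frame(station_id = city$stations$station_id,
                      x = city$stations$x, y = city$stations$y,
                      season = slot$season, day_type = slot$day_type,
                      hour = slot$hour, pm25 = y,
                      missing = missing, floored = floored & !missing,
                      stringsAsFactors = FALSE)
    class(out) <- c("observation_set", "data.frame")
    out
  })
}
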