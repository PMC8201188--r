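# Plain-text serialization: GeoJSON for vector layers, ESRI ASCII grid for
# rasters, CSV/JSON for tables, models and reports. Real data must arrive
# already projected to a planar metric CRS; coordinates are written as-is.

write_geojson_points <- function(df, path, crs = NULL) {
  props <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(crs)) fc$crs_note <- crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

write_geojson_lines <- function(lines, path, crs = NULL) {
  features <- lapply(lines$lines, function(l) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(lapply(seq_len(nrow(l$xy)),
                                                     function(i) l$xy[i, ]))),
         properties = list(class = l$class))
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(crs)) fc$crs_note <- crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

write_geojson_polygons <- function(polys, path, crs = NULL) {
  features <- lapply(polys$polys, function(p) {
    ring <- rbind(p$xy, p$xy[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(seq_len(nrow(ring)),
                                                          function(i) ring[i, ])))),
         properties = list(class = p$class))
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(crs)) fc$crs_note <- crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

#' Read a GeoJSON FeatureCollection into a package layer
#'
#' Supports Point collections (returned as [geo_points()]), LineString
#' collections ([geo_lines()]) and Polygon collections ([geo_polygons()];
#' outer rings only). Coordinates must already be planar metric.
#'
#' @param path GeoJSON file.
#' @param crs CRS identifier to attach.
#' @return a geo_points / geo_lines / geo_polygons layer.
#' @export
read_geojson_layer <- function(path, crs = "synthetic:meters") {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  types <- unique(vapply(fc$features, function(f) f$geometry$type, ""))
  if (length(types) != 1L) stop("mixed geometry types not supported")
  if (types == "Point") {
    rows <- lapply(fc$features, function(f) {
      cc <- unlist(f$geometry$coordinates)
      c(list(x = cc[1], y = cc[2]), f$properties)
    })
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    return(geo_points(df, crs))
  }
  if (types == "LineString") {
    lines <- lapply(fc$features, function(f) {
      xy <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
      list(xy = xy, class = f$properties$class)
    })
    return(geo_lines(lines, crs))
  }
  if (types == "Polygon") {
    polys <- lapply(fc$features, function(f) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      n <- nrow(ring)
      if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
      list(xy = ring, class = f$properties$class)
    })
    return(geo_polygons(polys, crs))
  }
  stop("unsupported geometry type: ", types)
}

#' Write a raster as an ESRI ASCII grid (plain text)
#' @param raster a [geo_raster()].
#' @param path output .asc file.
#' @export
write_ascii_grid <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", raster$ncol),
               paste("nrows", raster$nrow),
               paste("xllcorner", raster$xmin),
               paste("yllcorner", raster$ymin),
               paste("cellsize", raster$res),
               "NODATA_value -9999"), con)
  # ASCII grid rows run north -> south
  for (r in rev(seq_len(raster$nrow))) {
    writeLines(paste(raster$values[r, ], collapse = " "), con)
  }
}

#' Read an ESRI ASCII grid
#' @param path .asc file.
#' @param crs CRS identifier to attach.
#' @return a [geo_raster()].
#' @export
read_ascii_grid <- function(path, crs = "synthetic:meters") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == hdr$nodata_value] <- NA
  geo_raster(vals[rev(seq_len(nrow(vals))), , drop = FALSE],
             hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs)
}

#' Write a synthetic city to a directory of plain-text files
#'
#' GeoJSON per vector layer, ASCII grids for the rasters, CSVs for the
#' station tables and a JSON file for the generator configuration.
#'
#' @param city a `synthetic_city`.
#' @param dir output directory (created if needed).
#' @export
write_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(city$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  utils::write.csv(city$met_stations, file.path(dir, "met_stations.csv"),
                   row.names = FALSE)
  crs <- city$layers$crs
  write_geojson_points(city$layers$poi, file.path(dir, "poi.geojson"), crs)
  write_geojson_points(city$layers$industry,
                       file.path(dir, "industry.geojson"), crs)
  write_geojson_lines(city$layers$roads, file.path(dir, "roads.geojson"), crs)
  write_geojson_polygons(city$layers$landuse,
                         file.path(dir, "landuse.geojson"), crs)
  write_ascii_grid(city$layers$elevation, file.path(dir, "elevation.asc"))
  write_ascii_grid(city$layers$population, file.path(dir, "population.asc"))
  cfg <- city$config
  cfg$extent <- as.numeric(cfg$extent)
  jsonlite::write_json(unclass(cfg), file.path(dir, "city_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a city directory written by [write_city()]
#'
#' @param dir directory with the stations/met-stations CSVs, per-layer
#'   GeoJSON files, ASCII-grid rasters and city_config.json.
#' @return a `synthetic_city`-shaped list (layers, stations, met_stations,
#'   config as plain list).
#' @export
read_city <- function(dir) {
  stations <- utils::read.csv(file.path(dir, "stations.csv"),
                              stringsAsFactors = FALSE)
  met_stations <- utils::read.csv(file.path(dir, "met_stations.csv"),
                                  stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "city_config.json"),
                             simplifyVector = TRUE)
  crs <- "synthetic:meters"
  layers <- geo_layers(
    landuse = read_geojson_layer(file.path(dir, "landuse.geojson"), crs),
    roads = read_geojson_layer(file.path(dir, "roads.geojson"), crs),
    poi = read_geojson_layer(file.path(dir, "poi.geojson"), crs),
    industry = read_geojson_layer(file.path(dir, "industry.geojson"), crs),
    elevation = read_ascii_grid(file.path(dir, "elevation.asc"), crs),
    population = read_ascii_grid(file.path(dir, "population.asc"), crs),
    extent = as.numeric(cfg$extent), crs = crs)
  structure(list(layers = layers, stations = stations,
                 met_stations = met_stations, config = cfg),
            class = "synthetic_city")
}

#' Serialize / read the ground-truth coefficient map as JSON
#' @param truth a [synthetic_truth()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  out <- lapply(truth$slots, function(s)
    list(intercept = s$intercept, coefficients = as.list(s$coefficients),
         noise_sd = s$noise_sd))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @param spec a [buffer_spec()] naming the valid predictor schema.
#' @export
read_truth <- function(path, spec = buffer_spec()) {
  raw <- jsonlite::read_json(path)
  slots <- lapply(raw, function(s)
    list(intercept = s$intercept,
         coefficients = unlist(s$coefficients),
         noise_sd = s$noise_sd))
  synthetic_truth(slots, spec)
}

#' Write a predictor matrix as CSV plus a JSON column-metadata sidecar
#' @param X a `predictor_matrix`.
#' @param path output CSV path; the sidecar gets the same path + ".meta.json".
#' @export
write_predictor_matrix <- function(X, path) {
  df <- cbind(id = rownames(X), as.data.frame(X))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(attr(X, "meta"), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

lur_model_as_list <- function(model) {
  list(intercept = model$intercept,
       terms = model$terms, r2 = model$r2, adjusted_r2 = model$adjusted_r2,
       rmse = model$rmse, n_obs = model$n_obs,
       residual_sd = model$residual_sd)
}

#' Serialize a fitted model as JSON (terms in entry order)
#' @param model a `lur_model`.
#' @param path output JSON path.
#' @export
write_lur_model <- function(model, path) {
  jsonlite::write_json(lur_model_as_list(model), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Model terms as a published-table-shaped data frame
#'
#' One row per term plus an intercept row, with columns variable,
#' coefficient, t, sig, vif, partial_r2 — the layout used by published
#' hourly LUR model tables.
#'
#' @param model a `lur_model`.
#' @param slot_id slot label for the first column.
#' @export
model_terms_table <- function(model, slot_id = NA_character_) {
  out <- data.frame(slot = slot_id, variable = "Intercept",
                    coefficient = model$intercept, t = NA_real_,
                    sig = NA_real_, vif = NA_real_, partial_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(model$terms)) {
    out <- rbind(out, data.frame(
      slot = slot_id, variable = model$terms$name,
      coefficient = model$terms$coefficient, t = model$terms$t,
      sig = model$terms$p, vif = model$terms$vif,
      partial_r2 = model$terms$partial_r2, stringsAsFactors = FALSE))
  }
  out
}

#' Write all artifacts of a run report
#'
#' Per slot: model JSON, terms CSV, grid predictions CSV, predicted-vs-
#' observed scatter CSV, kriged surface ASCII grid; plus the run-level
#' summary and comparison CSVs and a provenance JSON.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "model_summary.csv"),
                   row.names = FALSE)
  if (nrow(report$comparisons)) {
    utils::write.csv(report$comparisons, file.path(dir, "slot_comparisons.csv"),
                     row.names = FALSE)
  }
  terms_tables <- list()
  for (s in report$slots) {
    if (!isTRUE(s$ok)) next
    sd <- file.path(dir, s$slot_id)
    dir.create(sd, showWarnings = FALSE)
    write_lur_model(s$model, file.path(sd, "model.json"))
    terms_tables[[s$slot_id]] <- model_terms_table(s$model, s$slot_id)
    utils::write.csv(s$grid_predictions, file.path(sd, "grid_predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(s$station_scatter, file.path(sd, "predicted_vs_observed.csv"),
                     row.names = FALSE)
    if (!is.null(s$surface)) {
      write_ascii_grid(s$surface$raster, file.path(sd, "surface.asc"))
    }
  }
  if (length(terms_tables)) {
    utils::write.csv(do.call(rbind, terms_tables),
                     file.path(dir, "model_terms.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
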