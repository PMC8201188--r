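# Lightweight S3 containers for the geospatial layers. Everything lives in
# one planar metric CRS; real data must arrive already projected (e.g. UTM).

LANDUSE_CLASSES <- c("arable", "garden", "woodland", "grassland",
                     "commercial_service", "industrial_mining", "residential")

ROAD_CLASSES <- c("primary_road", "secondary_road")

POI_CATEGORIES <- c("catering", "scenic_spots", "public_facilities",
                    "companies", "shopping", "transportation",
                    "financial_banks", "science_education",
                    "residential_housing", "life_services", "sports_leisure",
                    "medical_care", "government")

MET_VARIABLES <- c("temperature", "relative_humidity", "pressure", "wind_speed")

#' Default buffer radii (metres)
#'
#' Twelve concentric buffer radii used for every buffered predictor. The
#' largest, 3000 m, extends the classical 300-2500 m ladder because several
#' published hourly models retain `_3000` variables.
#'
#' @param radii_m strictly increasing positive radii in metres.
#' @return object of class `buffer_spec`.
#' @export
buffer_spec <- function(radii_m = c(300, 500, 600, 700, 800, 900, 1000,
                                    1300, 1500, 2000, 2500, 3000)) {
  if (any(radii_m <= 0)) stop("buffer radii must be positive")
  if (any(diff(radii_m) <= 0)) stop("buffer radii must be strictly increasing")
  structure(list(radii_m = radii_m), class = "buffer_spec")
}

crs_of <- function(x) attr(x, "crs", exact = TRUE)

check_crs <- function(a, b) {
  ca <- crs_of(a); cb <- crs_of(b)
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb)) {
    stop("CRS mismatch: '", ca, "' vs '", cb, "'")
  }
  invisible(TRUE)
}

#' Point layer
#' @param df data frame with numeric `x`, `y` columns (metres) and any
#'   attribute columns (e.g. `category`).
#' @param crs planar metric CRS identifier string.
#' @export
geo_points <- function(df, crs = "synthetic:meters") {
  stopifnot(is.data.frame(df), all(c("x", "y") %in% names(df)))
  structure(df, crs = crs, class = c("geo_points", "data.frame"))
}

#' Polyline layer
#' @param lines list; each element a list with `xy` (two-column vertex
#'   matrix) and `class` (road class string).
#' @param crs planar metric CRS identifier string.
#' @export
geo_lines <- function(lines, crs = "synthetic:meters") {
  structure(list(lines = lines), crs = crs, class = "geo_lines")
}

#' Polygon layer
#' @param polys list; each element a list with `xy` (two-column vertex
#'   matrix, simple ring) and `class` (land-use class string).
#' @param crs planar metric CRS identifier string.
#' @export
geo_polygons <- function(polys, crs = "synthetic:meters") {
  polys <- lapply(polys, function(p) {
    if (is.null(p$bbox)) p$bbox <- bbox_of(p$xy)
    p
  })
  structure(list(polys = polys), crs = crs, class = "geo_polygons")
}

#' Regular grid raster
#'
#' Row `r`, column `c` of `values` covers the cell with lower-left corner
#' `(xmin + (c-1)*res, ymin + (r-1)*res)`; y grows with the row index.
#'
#' @param values numeric matrix (nrow = rows in y, ncol = columns in x).
#' @param xmin,ymin lower-left corner of the grid (metres).
#' @param res cell size in metres.
#' @param crs planar metric CRS identifier string.
#' @export
geo_raster <- function(values, xmin, ymin, res, crs = "synthetic:meters") {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res,
                 nrow = nrow(values), ncol = ncol(values)),
            crs = crs, class = "geo_raster")
}

raster_extent <- function(r) {
  c(r$xmin, r$ymin, r$xmin + r$ncol * r$res, r$ymin + r$nrow * r$res)
}

#' Bundle of environmental layers sharing one CRS
#'
#' @param landuse `geo_polygons` with classes in the seven-class land-use
#'   enumeration; roads `geo_lines` (primary/secondary); poi `geo_points`
#'   with a `category` column (13 categories); industry `geo_points`;
#'   elevation, population `geo_raster`s.
#' @param landuse,roads,poi,industry,elevation,population layers as above.
#' @param extent numeric c(xmin, ymin, xmax, ymax).
#' @param crs shared planar metric CRS identifier.
#' @return object of class `geo_layers`.
#' @export
geo_layers <- function(landuse, roads, poi, industry, elevation, population,
                       extent, crs = "synthetic:meters") {
  for (lay in list(landuse, roads, poi, industry, elevation, population)) {
    if (!identical(crs_of(lay), crs)) {
      stop("all layers of a geo_layers set must share the CRS '", crs, "'")
    }
  }
  bad <- setdiff(unique(vapply(landuse$polys, `[[`, "", "class")), LANDUSE_CLASSES)
  if (length(bad)) stop("unknown land-use class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(vapply(roads$lines, `[[`, "", "class")), ROAD_CLASSES)
  if (length(bad)) stop("unknown road class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(poi$category)), POI_CATEGORIES)
  if (length(bad)) stop("unknown POI category: ", paste(bad, collapse = ", "))
  structure(list(landuse = landuse, roads = roads, poi = poi,
                 industry = industry, elevation = elevation,
                 population = population, extent = extent, crs = crs),
            class = "geo_layers")
}

#' @export
print.geo_layers <- function(x, ...) {
  cat("<geo_layers> CRS:", x$crs, "\n")
  cat("  extent:", paste(round(x$extent), collapse = ", "), "(m)\n")
  cat("  landuse polygons:", length(x$landuse$polys),
      "| road polylines:", length(x$roads$lines),
      "| POI points:", nrow(x$poi),
      "| industry points:", nrow(x$industry), "\n")
  cat("  elevation raster:", x$elevation$nrow, "x", x$elevation$ncol,
      "@", x$elevation$res, "m |",
      "population raster:", x$population$nrow, "x", x$population$ncol,
      "@", x$population$res, "m\n")
  invisible(x)
}

#' The 12 modelling slots
#'
#' Season (heating / non-heating) crossed with day type (working /
#' non-working) and hour (0, 8, 18): midnight, morning rush, evening rush.
#'
#' @return data frame with columns season, day_type, hour and a slot id.
#' @export
slot_table <- function() {
  g <- expand.grid(hour = c(0L, 8L, 18L),
                   day_type = c("working", "non_working"),
                   season = c("heating", "non_heating"),
                   stringsAsFactors = FALSE)
  g <- g[, c("season", "day_type", "hour")]
  g$slot_id <- paste(g$season, g$day_type, g$hour, sep = "_")
  g
}

#' Construct/validate one slot
#' @param season "heating" or "non_heating".
#' @param day_type "working" or "non_working".
#' @param hour one of 0, 8, 18.
#' @export
slot <- function(season, day_type, hour) {
  season <- match.arg(season, c("heating", "non_heating"))
  day_type <- match.arg(day_type, c("working", "non_working"))
  if (!hour %in% c(0L, 8L, 18L)) stop("hour must be one of 0, 8, 18")
  structure(list(season = season, day_type = day_type, hour = as.integer(hour),
                 slot_id = paste(season, day_type, hour, sep = "_")),
            class = "pm_slot")
}

as_slot <- function(x) {
  if (inherits(x, "pm_slot")) return(x)
  if (is.character(x) && length(x) == 1L) {
    tab <- slot_table()
    i <- match(x, tab$slot_id)
    if (is.na(i)) stop("unknown slot id '", x, "'")
    return(slot(tab$season[i], tab$day_type[i], tab$hour[i]))
  }
  if (is.list(x)) return(slot(x$season, x$day_type, x$hour))
  stop("cannot interpret object as a slot")
}
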