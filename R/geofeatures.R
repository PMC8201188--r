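# Buffer-based predictor extraction: counts of points, lengths of road
# polylines and areas of land-use polygons inside concentric circular
# buffers around each target, plus point-sampled rasters and kriged
# meteorological covariates.

BUFFERED_BASES <- function() c(LANDUSE_CLASSES, ROAD_CLASSES, POI_CATEGORIES, "industry")

UNBUFFERED_VARS <- function() c("elevation", "population", MET_VARIABLES)

#' All predictor-matrix column names for a buffer specification
#'
#' One column per (base variable, radius) pair — 7 land-use classes, 2 road
#' classes, 13 POI categories and industrial sources — plus the six
#' unbuffered columns (elevation, population and four meteorological
#' variables), in a fixed deterministic order.
#'
#' @param spec a [buffer_spec()].
#' @return character vector of column names, e.g. `"catering_900"`.
#' @export
predictor_names <- function(spec = buffer_spec()) {
  buffered <- as.vector(t(outer(BUFFERED_BASES(), spec$radii_m, paste, sep = "_")))
  c(buffered, UNBUFFERED_VARS())
}

variable_units <- function(base) {
  switch(base,
         elevation = "m", population = "persons",
         temperature = "degC", relative_humidity = "percent",
         pressure = "hPa", wind_speed = "m_s",
         primary_road = "m", secondary_road = "m",
         if (base %in% LANDUSE_CLASSES) "m2" else "count")
}

parse_variable <- function(name) {
  if (name %in% UNBUFFERED_VARS()) {
    return(list(base = name, radius = NA_real_))
  }
  m <- regmatches(name, regexec("^(.*)_([0-9]+)$", name))[[1]]
  if (length(m) == 3L && m[2] %in% BUFFERED_BASES()) {
    return(list(base = m[2], radius = as.numeric(m[3])))
  }
  stop("unknown predictor variable '", name, "'")
}

# --- elementary buffer operations ------------------------------------------

#' Count points inside a circular buffer
#'
#' Boundary inclusive: a point at exactly the buffer radius is counted,
#' which makes counts exactly nondecreasing in the radius.
#'
#' @param points a [geo_points()] layer (or data frame with x, y).
#' @param center numeric c(x, y) in the layer CRS.
#' @param radius_m buffer radius, metres.
#' @return integer count.
#' @export
buffer_point_count <- function(points, center, radius_m) {
  if (radius_m <= 0) stop("radius_m must be positive")
  check_crs(points, center)
  if (nrow(points) == 0L) return(0L)
  d2 <- (points$x - center[1])^2 + (points$y - center[2])^2
  sum(d2 <= radius_m^2)
}

#' Total road length inside a circular buffer
#'
#' Length of the geometric intersection of the polylines with the closed
#' disk, via the closed-form segment-disk intersection.
#'
#' @param lines a [geo_lines()] layer.
#' @param center numeric c(x, y).
#' @param radius_m buffer radius, metres.
#' @return length in metres.
#' @export
buffer_line_length <- function(lines, center, radius_m) {
  if (radius_m <= 0) stop("radius_m must be positive")
  check_crs(lines, center)
  segs <- segment_table(lines)
  if (nrow(segs) == 0L) return(0)
  sum(segments_disk_length(segs$x1, segs$y1, segs$x2, segs$y2,
                           center[1], center[2], radius_m))
}

# flatten a polyline layer into a segment table (cached on the object)
segment_table <- function(lines) {
  cached <- attr(lines, "segment_table", exact = TRUE)
  if (!is.null(cached)) return(cached)
  parts <- lapply(lines$lines, function(l) {
    xy <- l$xy
    n <- nrow(xy)
    if (n < 2L) return(NULL)
    data.frame(x1 = xy[-n, 1], y1 = xy[-n, 2], x2 = xy[-1, 1], y2 = xy[-1, 2],
               class = l$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(x1 = numeric(0), y1 = numeric(0),
                                      x2 = numeric(0), y2 = numeric(0),
                                      class = character(0))
  out
}

#' Total polygon area inside a circular buffer
#'
#' Area of the intersection of the layer's polygons with the closed disk;
#' the disk is approximated by a 256-segment polygon (relative area error
#' about 1e-4) and intersections are computed by Sutherland-Hodgman
#' clipping against the convex circle polygon.
#'
#' @param polygons a [geo_polygons()] layer.
#' @param center numeric c(x, y).
#' @param radius_m buffer radius, metres.
#' @return area in square metres (at most pi * radius_m^2).
#' @export
buffer_polygon_area <- function(polygons, center, radius_m) {
  if (radius_m <= 0) stop("radius_m must be positive")
  check_crs(polygons, center)
  circ <- circle_polygon(center, radius_m)
  total <- 0
  for (p in polygons$polys) {
    if (!bbox_intersects_disk(p$bbox, center[1], center[2], radius_m)) next
    clipped <- clip_polygon_convex(p$xy, circ)
    if (nrow(clipped) >= 3L) total <- total + polygon_area(clipped)
  }
  total
}

#' Sample a raster at point locations (nearest cell)
#'
#' @param raster a [geo_raster()].
#' @param points data frame with x, y (and optionally station_id, used in
#'   error messages).
#' @return numeric vector of cell values.
#' @export
raster_sample <- function(raster, points) {
  ext <- raster_extent(raster)
  outside <- points$x < ext[1] | points$x > ext[3] |
    points$y < ext[2] | points$y > ext[4]
  if (any(outside)) {
    ids <- if (!is.null(points$station_id)) points$station_id[outside] else which(outside)
    stop("points outside raster extent: ", paste(utils::head(ids, 5), collapse = ", "))
  }
  col <- pmin(pmax(floor((points$x - raster$xmin) / raster$res) + 1L, 1L), raster$ncol)
  row <- pmin(pmax(floor((points$y - raster$ymin) / raster$res) + 1L, 1L), raster$nrow)
  raster$values[cbind(row, col)]
}

# --- batch extraction -------------------------------------------------------

# Compute the named variables at every target, grouping work by base
# variable so distance matrices and polygon clips are shared across radii.
extract_variables <- function(layers, targets, vars, met_values = NULL) {
  parsed <- lapply(vars, parse_variable)
  bases <- vapply(parsed, `[[`, "", "base")
  radii <- vapply(parsed, `[[`, 0, "radius")
  nt <- nrow(targets)
  out <- matrix(0, nrow = nt, ncol = length(vars),
                dimnames = list(NULL, vars))

  # POI / industry counts
  for (b in intersect(unique(bases), c(POI_CATEGORIES, "industry"))) {
    idx <- which(bases == b)
    pts <- if (b == "industry") layers$industry else
      layers$poi[layers$poi$category == b, , drop = FALSE]
    if (nrow(pts) == 0L) next
    # chunk targets to bound the distance-matrix memory
    chunk <- max(1L, floor(2e7 / max(nrow(pts), 1L)))
    for (s in seq(1L, nt, by = chunk)) {
      e <- min(s + chunk - 1L, nt)
      d2 <- outer(targets$x[s:e], pts$x, "-")^2 +
        outer(targets$y[s:e], pts$y, "-")^2
      for (j in idx) out[s:e, j] <- rowSums(d2 <= radii[j]^2)
    }
  }

  # road lengths
  road_bases <- intersect(unique(bases), ROAD_CLASSES)
  if (length(road_bases)) {
    segs <- segment_table(layers$roads)
    for (b in road_bases) {
      idx <- which(bases == b)
      sb <- segs[segs$class == b, , drop = FALSE]
      if (nrow(sb) == 0L) next
      for (i in seq_len(nt)) {
        for (j in idx) {
          out[i, j] <- sum(segments_disk_length(sb$x1, sb$y1, sb$x2, sb$y2,
                                                targets$x[i], targets$y[i],
                                                radii[j]))
        }
      }
    }
  }

  # land-use areas: one clip pass per (target, radius), attributed per class
  lu_bases <- intersect(unique(bases), LANDUSE_CLASSES)
  if (length(lu_bases)) {
    lu_radii <- sort(unique(radii[bases %in% lu_bases]))
    polys <- layers$landuse$polys
    pb <- t(vapply(polys, `[[`, numeric(4), "bbox"))
    pcl <- vapply(polys, `[[`, "", "class")
    for (i in seq_len(nt)) {
      cx <- targets$x[i]; cy <- targets$y[i]
      for (r in lu_radii) {
        jj <- which(radii == r & bases %in% lu_bases)
        cand <- which(bbox_intersects_disk_vec(pb, cx, cy, r) &
                        pcl %in% lu_bases)
        if (!length(cand)) next
        circ <- circle_polygon(c(cx, cy), r)
        areas <- stats::setNames(numeric(length(lu_bases)), lu_bases)
        for (k in cand) {
          # convex cells (the Voronoi mosaic) clip the 256-gon circle
          # against the cell: far fewer Sutherland-Hodgman passes
          clipped <- if (isTRUE(polys[[k]]$convex)) {
            clip_polygon_convex(circ, polys[[k]]$xy)
          } else {
            clip_polygon_convex(polys[[k]]$xy, circ)
          }
          if (nrow(clipped) >= 3L) {
            areas[pcl[k]] <- areas[pcl[k]] + polygon_area(clipped)
          }
        }
        for (j in jj) out[i, j] <- areas[[bases[j]]]
      }
    }
  }

  # unbuffered rasters and met covariates
  if ("elevation" %in% bases) {
    out[, which(bases == "elevation")] <- raster_sample(layers$elevation, targets)
  }
  if ("population" %in% bases) {
    out[, which(bases == "population")] <- raster_sample(layers$population, targets)
  }
  for (v in intersect(unique(bases), MET_VARIABLES)) {
    if (is.null(met_values) || is.null(met_values[[v]])) {
      stop("variable '", v, "' requires met_values (kriged meteorology)")
    }
    out[, which(bases == v)] <- met_values[[v]]
  }
  as.data.frame(out)
}

bbox_intersects_disk_vec <- function(bb, cx, cy, r) {
  ddx <- pmax(bb[, 1] - cx, 0, cx - bb[, 3])
  ddy <- pmax(bb[, 2] - cy, 0, cy - bb[, 4])
  ddx * ddx + ddy * ddy <= r * r
}

#' Build the full stations-by-predictors matrix
#'
#' One column per (base variable, radius) pair for land use, roads, POIs
#' and industrial sources, plus unbuffered elevation, population and (when
#' `met_values` is supplied) the four kriged meteorological covariates.
#' Column order is deterministic: buffered bases in schema order with radii
#' ascending, then the unbuffered block.
#'
#' @param layers a [geo_layers()] set.
#' @param targets data frame with station_id (or id), x, y.
#' @param spec a [buffer_spec()].
#' @param met_values optional data frame aligned with `targets` holding the
#'   kriged meteorological covariates (see [krige_met()]); if absent the met
#'   columns are omitted.
#' @return data frame of class `predictor_matrix`; row names are target
#'   ids, attribute `meta` is a data frame (name, base, radius_m, units).
#' @export
build_predictor_matrix <- function(layers, targets, spec = buffer_spec(),
                                   met_values = NULL) {
  vars <- predictor_names(spec)
  if (is.null(met_values)) vars <- setdiff(vars, MET_VARIABLES)
  X <- extract_variables(layers, targets, vars, met_values)
  ids <- if (!is.null(targets$station_id)) targets$station_id else
    as.character(seq_len(nrow(targets)))
  rownames(X) <- ids
  meta <- do.call(rbind, lapply(vars, function(v) {
    p <- parse_variable(v)
    data.frame(name = v, base = p$base, radius_m = p$radius,
               units = variable_units(p$base), stringsAsFactors = FALSE)
  }))
  attr(X, "meta") <- meta
  class(X) <- c("predictor_matrix", "data.frame")
  X
}
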