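# Shared fixtures and independent oracles for the test suite.

# A reduced city: 20 km extent, down-scaled POI processes. Big enough for
# buffer geometry at the default radii, small enough to build in well under
# a second.
tiny_city_config <- function(seed = 1L, n_stations = 15L,
                             poi_mean_counts =
                               round(default_poi_mean_counts() / 15), ...) {
  city_config(extent = c(0, 0, 20000, 20000),
              n_stations = n_stations,
              poi_mean_counts = poi_mean_counts,
              poi_decay_m = 6000,
              n_industry = 150L,
              road_spec = list(n_rings = 3L, n_radials = 6L, n_secondary = 60L),
              landuse_seeds_per_class = 4L,
              elevation_res_m = 500, population_res_m = 500,
              rng_seed = seed, ...)
}

.city_cache <- new.env(parent = emptyenv())

cached_tiny_city <- function(seed = 1L) {
  key <- paste0("tiny_", seed)
  if (is.null(.city_cache[[key]])) {
    .city_cache[[key]] <- generate_city(tiny_city_config(seed))
  }
  .city_cache[[key]]
}

# Independent even-odd point-in-polygon (distinct code path from the
# Sutherland-Hodgman clipping under test).
oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# Monte-Carlo point-sampling oracle for the area of (union of polygons)
# inside a disk: a jittered lattice over the disk's bounding square
# (stratified sampling keeps the boundary-driven error well below the test
# tolerances at 100k points). Polygons are assumed non-overlapping.
mc_disk_area <- function(polys, center, r, n = 100000L) {
  m <- floor(sqrt(n))
  g <- (seq_len(m) - 1) / m
  px <- center[1] - r + (rep(g, each = m) + runif(m * m) / m) * 2 * r
  py <- center[2] - r + (rep(g, times = m) + runif(m * m) / m) * 2 * r
  in_disk <- (px - center[1])^2 + (py - center[2])^2 <= r^2
  hits <- rep(FALSE, m * m)
  for (p in polys) hits <- hits | oracle_point_in_poly(px, py, p$xy)
  mean(hits & in_disk) * (2 * r)^2
}

# Monte-Carlo oracle for total segment length inside a disk: sample points
# uniformly along each segment.
mc_disk_length <- function(segs, center, r, n_per_seg = 2000L) {
  tot <- 0
  for (k in seq_len(nrow(segs))) {
    t <- (seq_len(n_per_seg) - 0.5) / n_per_seg
    px <- segs$x1[k] + t * (segs$x2[k] - segs$x1[k])
    py <- segs$y1[k] + t * (segs$y2[k] - segs$y1[k])
    len <- sqrt((segs$x2[k] - segs$x1[k])^2 + (segs$y2[k] - segs$y1[k])^2)
    inside <- (px - center[1])^2 + (py - center[2])^2 <= r^2
    tot <- tot + mean(inside) * len
  }
  tot
}

# random convex-polygon scene (Voronoi mosaic of a few seeds) for oracle
# comparisons
random_scene <- function(seed, box = 5000) {
  set.seed(seed)
  seeds <- cbind(runif(6, 0, box), runif(6, 0, box))
  cells <- pmlur:::voronoi_cells(seeds, c(0, 0, box, box))
  polys <- lapply(cells, function(p) list(xy = p, bbox = pmlur:::bbox_of(p)))
  segs <- data.frame(x1 = runif(20, 0, box), y1 = runif(20, 0, box),
                     x2 = runif(20, 0, box), y2 = runif(20, 0, box),
                     class = "primary_road")
  center <- c(runif(1, 0.3, 0.7) * box, runif(1, 0.3, 0.7) * box)
  # cells ordered by seed distance to the buffer center, so tests can take
  # the nearest cells and compare areas at substantial disk coverage
  # (a relative tolerance is meaningless on a corner sliver)
  ord <- order((seeds[, 1] - center[1])^2 + (seeds[, 2] - center[2])^2)
  list(polys = polys[ord], segs = segs, center = center)
}
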