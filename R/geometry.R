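# Planar geometry primitives used by the buffer-extraction layer.
# All coordinates are Euclidean metres in a shared planar CRS; no geodesy.

#' Regular polygon approximating a circle
#'
#' Circles are represented as 256-segment regular polygons for all polygon
#' intersection work; the relative area error of the approximation is about
#' 1e-4, well below the 1e-3 tolerances used elsewhere.
#'
#' @param center numeric length-2 (x, y) in metres.
#' @param radius_m positive radius in metres.
#' @param n number of segments.
#' @return two-column matrix of vertices, counter-clockwise, not closed.
#' @keywords internal
circle_polygon <- function(center, radius_m, n = 256L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius_m * cos(theta), center[2] + radius_m * sin(theta))
}

#' Signed polygon area (shoelace formula)
#' @param xy two-column vertex matrix (not necessarily closed).
#' @return signed area, positive for counter-clockwise rings.
#' @keywords internal
polygon_signed_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

# Clip a polygon against the half-plane a*x + b*y <= c (Sutherland-Hodgman
# single-edge step). Returns a vertex matrix, possibly with 0 rows.
clip_halfplane <- function(xy, a, b, cc) {
  n <- nrow(xy)
  if (is.null(n) || n == 0L) return(xy)
  x <- xy[, 1]; y <- xy[, 2]
  f <- a * x + b * y - cc                    # <= 0 means inside
  inside <- f <= 0
  if (all(inside)) return(xy)
  if (!any(inside)) return(xy[0, , drop = FALSE])
  jp <- c(n, seq_len(n - 1L))                # previous vertex index
  fp <- f[jp]; insp <- inside[jp]
  crossing <- insp != inside                 # edge (prev -> this) crosses
  t <- ifelse(crossing, fp / (fp - f), 0)
  xi <- x[jp] + t * (x - x[jp])
  yi <- y[jp] + t * (y - y[jp])
  # per vertex emit: crossing point first, then the vertex itself if inside
  sel <- as.vector(rbind(crossing, inside))
  cbind(as.vector(rbind(xi, x))[sel], as.vector(rbind(yi, y))[sel])
}

# Intersection of an arbitrary simple polygon with a convex clipper
# (Sutherland-Hodgman). The clipper must be counter-clockwise.
clip_polygon_convex <- function(subject, clipper) {
  if (polygon_signed_area(clipper) < 0) clipper <- clipper[rev(seq_len(nrow(clipper))), , drop = FALSE]
  out <- subject
  m <- nrow(clipper)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    # inside of CCW edge (p_i -> p_j) is the left side: cross >= 0
    ex <- clipper[j, 1] - clipper[i, 1]
    ey <- clipper[j, 2] - clipper[i, 2]
    # left side: ex*(y - yi) - ey*(x - xi) >= 0  <=>  ey*x - ex*y <= ey*xi - ex*yi
    out <- clip_halfplane(out, ey, -ex, ey * clipper[i, 1] - ex * clipper[i, 2])
    if (nrow(out) == 0L) break
  }
  out
}

# Length of the intersection of segments with the closed disk of given
# center/radius. Inputs are vectors of segment endpoints; fully vectorised.
segments_disk_length <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx * dx + dy * dy
  px <- x1 - cx; py <- y1 - cy
  b <- 2 * (dx * px + dy * py)
  cc <- px * px + py * py - r * r
  len <- sqrt(a)
  out <- numeric(length(x1))
  deg <- a <= 0                      # degenerate zero-length segments
  disc <- b * b - 4 * a * cc
  hit <- !deg & disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- pmax((-b[hit] - sq) / (2 * a[hit]), 0)
    t2 <- pmin((-b[hit] + sq) / (2 * a[hit]), 1)
    out[hit] <- pmax(t2 - t1, 0) * len[hit]
  }
  out
}

# Vectorised ray-casting point-in-polygon (boundary treatment approximate;
# used for sampling-style checks, not exact predicates).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Voronoi cell of each seed inside a rectangular extent, by successive
# half-plane clipping against perpendicular bisectors. Cells are convex and
# tile the extent exactly. Returns a list of vertex matrices.
voronoi_cells <- function(seeds, extent) {
  rect <- cbind(c(extent[1], extent[3], extent[3], extent[1]),
                c(extent[2], extent[2], extent[4], extent[4]))
  n <- nrow(seeds)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- rect
    si <- seeds[i, ]
    # clip against nearer seeds first to shrink the cell quickly
    d2 <- (seeds[, 1] - si[1])^2 + (seeds[, 2] - si[2])^2
    for (j in order(d2)) {
      if (j == i) next
      sj <- seeds[j, ]
      a <- sj[1] - si[1]; b <- sj[2] - si[2]
      cc <- (sj[1]^2 - si[1]^2 + sj[2]^2 - si[2]^2) / 2
      cell <- clip_halfplane(cell, a, b, cc)
      if (nrow(cell) == 0L) break
    }
    cells[[i]] <- cell
  }
  cells
}

bbox_of <- function(xy) c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))

bbox_intersects_disk <- function(bb, cx, cy, r) {
  ddx <- pmax(bb[1] - cx, 0, cx - bb[3])
  ddy <- pmax(bb[2] - cy, 0, cy - bb[4])
  ddx * ddx + ddy * ddy <= r * r
}
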