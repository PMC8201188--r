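# Regression mapping: evaluate a fitted model on a coarse grid, krige the
# grid predictions into a continuous surface, and score predictions at the
# monitoring stations.

#' Cell centers of an axis-aligned grid over an extent
#'
#' The grid is anchored at the extent's lower-left corner; a cell is
#' represented by its center and kept when the center lies strictly inside
#' the extent. If the extent is smaller than the spacing (no center would
#' fall inside), the single extent midpoint is returned.
#'
#' @param extent numeric c(xmin, ymin, xmax, ymax).
#' @param spacing_m grid spacing, metres (default 3 km).
#' @return data frame: id, x, y.
#' @export
make_grid <- function(extent, spacing_m = 3000) {
  if (spacing_m <= 0) stop("spacing_m must be positive")
  if (extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("degenerate extent")
  }
  axis_centers <- function(lo, hi) {
    if (lo + spacing_m / 2 >= hi) return(numeric(0))
    s <- seq(lo + spacing_m / 2, hi, by = spacing_m)
    s[s < hi]
  }
  xs <- axis_centers(extent[1], extent[3])
  ys <- axis_centers(extent[2], extent[4])
  if (!length(xs)) xs <- (extent[1] + extent[3]) / 2
  if (!length(ys)) ys <- (extent[2] + extent[4]) / 2
  g <- expand.grid(x = xs, y = ys)
  data.frame(id = sprintf("G%05d", seq_len(nrow(g))), x = g$x, y = g$y,
             stringsAsFactors = FALSE)
}

#' Evaluate a fitted LUR model on grid points
#'
#' Extracts every model term at the grid points (buffered features from the
#' layers; meteorological covariates kriged to the grid) and evaluates the
#' regression equation. Negative predictions are clamped to zero (physical
#' concentrations) and counted.
#'
#' @param model a `lur_model`.
#' @param layers a [geo_layers()] set.
#' @param grid data frame from [make_grid()] (id, x, y).
#' @param met optional met-station table (from [generate_meteorology()] or
#'   real data); required when the model contains meteorological terms.
#' @return data frame: id, x, y, prediction; attribute `n_clamped`.
#' @export
predict_surface <- function(model, layers, grid, met = NULL) {
  vars <- model$terms$name
  met_vars <- intersect(vapply(vars, function(v) parse_variable(v)$base, ""),
                        MET_VARIABLES)
  met_values <- NULL
  if (length(met_vars)) {
    if (is.null(met)) {
      stop("model terms need meteorology (", paste(met_vars, collapse = ", "),
           ") but no met table was supplied")
    }
    met_values <- krige_met(met, grid)
  }
  X <- if (length(vars)) extract_variables(layers, grid, vars, met_values)
  else as.data.frame(matrix(numeric(0), nrow = nrow(grid), ncol = 0))
  pred <- predict(model, X)
  n_clamped <- sum(pred < 0)
  pred <- pmax(pred, 0)
  out <- data.frame(id = grid$id, x = grid$x, y = grid$y, prediction = pred,
                    stringsAsFactors = FALSE)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Krige grid predictions into a continuous raster
#'
#' Fits a variogram to the grid predictions and interpolates them to a
#' finer raster by ordinary kriging. With a zero-nugget fit the raster
#' reproduces the grid predictions at the grid centers.
#'
#' @param grid_pred data frame from [predict_surface()] (x, y, prediction).
#' @param extent numeric c(xmin, ymin, xmax, ymax) the raster must cover.
#' @param fine_resolution_m output cell size, metres.
#' @param model variogram family for the fit.
#' @param force_zero_nugget set the fitted nugget to zero, making the
#'   kriged surface an exact interpolator of the grid predictions (the
#'   mapped surface is a deterministic regression evaluation, so a zero
#'   nugget is usually the right choice).
#' @return list: `raster` (a [geo_raster()]), `variogram`.
#' @export
krige_surface <- function(grid_pred, extent, fine_resolution_m = 500,
                          model = "spherical", force_zero_nugget = FALSE) {
  if (nrow(grid_pred) < 3L) stop("need at least 3 grid predictions")
  field <- data.frame(x = grid_pred$x, y = grid_pred$y,
                      value = grid_pred$prediction)
  if (stats::sd(field$value) == 0) {
    nc <- max(1L, ceiling((extent[3] - extent[1]) / fine_resolution_m))
    nr <- max(1L, ceiling((extent[4] - extent[2]) / fine_resolution_m))
    vals <- matrix(field$value[1], nr, nc)
    return(list(raster = geo_raster(vals, extent[1], extent[2],
                                    fine_resolution_m),
                variogram = make_variogram(model, 0, 0, 1)))
  }
  emp <- empirical_variogram(field, n_bins = 12L)
  vg <- fit_variogram(emp, model)
  if (force_zero_nugget) {
    vg <- make_variogram(vg$model, 0, max(vg$sill - vg$nugget, 1e-12),
                         vg$range_m)
  }
  nc <- max(1L, ceiling((extent[3] - extent[1]) / fine_resolution_m))
  nr <- max(1L, ceiling((extent[4] - extent[2]) / fine_resolution_m))
  xc <- extent[1] + (seq_len(nc) - 0.5) * fine_resolution_m
  yc <- extent[2] + (seq_len(nr) - 0.5) * fine_resolution_m
  targets <- expand.grid(x = xc, y = yc)
  pred <- ok_predict(field, vg, targets)$prediction
  vals <- matrix(pred, nrow = nr, ncol = nc, byrow = TRUE)
  list(raster = geo_raster(vals, extent[1], extent[2], fine_resolution_m),
       variogram = vg)
}

#' Relative error of the mean prediction at the stations
#'
#' 100 * (mean(predicted) - mean(observed)) / mean(observed), in percent.
#'
#' @param predicted,observed aligned nonempty vectors.
#' @return percent relative error of the means.
#' @export
station_relative_error <- function(predicted, observed) {
  keep <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[keep]; observed <- observed[keep]
  if (!length(observed)) stop("no aligned observations")
  if (mean(observed) == 0) stop("zero observed mean")
  100 * (mean(predicted) - mean(observed)) / mean(observed)
}
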