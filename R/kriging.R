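# Ordinary kriging engine: empirical semivariogram, weighted-least-squares
# variogram fitting (spherical / exponential / gaussian), and the ordinary
# kriging predictor with unit-sum weights. Used both to interpolate the
# meteorological covariates to stations/grid and to smooth the
# regression-mapped concentration surface.

#' Theoretical semivariance of a fitted model
#'
#' Conventions: gamma(0) = 0; for h > 0 the nugget acts as a discontinuity.
#' `range_m` is the distance at which the spherical model reaches its sill;
#' for the exponential and gaussian models it is the e-folding length
#' (gamma approaches the sill asymptotically).
#'
#' @param vg a `variogram` object (see [fit_variogram()]).
#' @param h numeric vector of distances (metres).
#' @return semivariance values.
#' @export
variogram_semivariance <- function(vg, h) {
  n <- vg$nugget; s <- vg$sill; a <- vg$range_m
  ps <- s - n
  g <- switch(vg$model,
              spherical = ifelse(h >= a, ps,
                                 ps * (1.5 * h / a - 0.5 * (h / a)^3)),
              exponential = ps * (1 - exp(-h / a)),
              gaussian = ps * (1 - exp(-(h / a)^2)),
              stop("unknown variogram model '", vg$model, "'"))
  out <- n + g
  out[h == 0] <- 0
  out
}

make_variogram <- function(model, nugget, sill, range_m) {
  model <- match.arg(model, c("spherical", "exponential", "gaussian"))
  if (nugget < 0 || sill < nugget || range_m <= 0) {
    stop("variogram requires 0 <= nugget <= sill and range_m > 0")
  }
  structure(list(model = model, nugget = nugget, sill = sill,
                 range_m = range_m), class = "variogram")
}

#' @export
print.variogram <- function(x, ...) {
  cat(sprintf("<variogram> %s: nugget %.4g, sill %.4g, range %.4g m\n",
              x$model, x$nugget, x$sill, x$range_m))
  invisible(x)
}

#' Empirical (binned) semivariogram
#'
#' Bin semivariance is the mean over point pairs in the distance bin of
#' half the squared value difference; bins with no pairs are dropped.
#'
#' @param field data frame with x, y, value.
#' @param n_bins number of equal-width distance bins.
#' @param max_dist maximum pair distance considered; default half the
#'   maximum inter-point distance.
#' @return data frame: dist (bin mean distance), gamma, n_pairs.
#' @export
empirical_variogram <- function(field, n_bins = 12L, max_dist = NULL) {
  if (nrow(field) < 2L) stop("need at least 2 points")
  d <- stats::dist(field[, c("x", "y")])
  dv <- stats::dist(field$value)
  d <- as.numeric(d); dv <- as.numeric(dv)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) stop("max_dist must be positive")
  keep <- d <= max_dist & d > 0
  d <- d[keep]; dv <- dv[keep]
  if (!length(d)) stop("no point pairs within max_dist")
  bin <- pmin(pmax(ceiling(d / (max_dist / n_bins)), 1L), n_bins)
  gamma <- tapply(0.5 * dv^2, bin, mean)
  dist_mean <- tapply(d, bin, mean)
  n_pairs <- tapply(d, bin, length)
  data.frame(dist = as.numeric(dist_mean), gamma = as.numeric(gamma),
             n_pairs = as.integer(n_pairs))
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises the pair-count-weighted squared error between the empirical
#' semivariances and the model curve over (nugget, partial sill, range)
#' under nonnegativity constraints, from a small deterministic grid of
#' starting points. Degenerate all-zero semivariances yield a nugget-only
#' (flat) model with a warning.
#'
#' @param empirical output of [empirical_variogram()].
#' @param model "spherical" (default), "exponential" or "gaussian".
#' @return a `variogram` object.
#' @export
fit_variogram <- function(empirical, model = "spherical") {
  model <- match.arg(model, c("spherical", "exponential", "gaussian"))
  emp <- empirical[empirical$n_pairs > 0, , drop = FALSE]
  if (nrow(emp) < 3L) stop("need at least 3 non-empty variogram bins")
  if (all(emp$gamma <= 0)) {
    warning("all empirical semivariances are zero; returning nugget-only model")
    return(make_variogram(model, 0, 0, max(emp$dist)))
  }
  w <- emp$n_pairs
  obj <- function(par) {
    vg <- list(model = model, nugget = par[1], sill = par[1] + par[2],
               range_m = par[3])
    class(vg) <- "variogram"
    g <- variogram_semivariance(vg, emp$dist)
    sum(w * (g - emp$gamma)^2)
  }
  gmax <- max(emp$gamma); dmax <- max(emp$dist)
  starts <- expand.grid(nugget = c(0, 0.1 * gmax),
                        psill = c(0.5, 1) * gmax,
                        range = c(0.25, 0.5, 1) * dmax)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                            lower = c(0, 0, 1e-6 * dmax),
                            upper = c(2 * gmax, 5 * gmax, 10 * dmax)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed")
  p <- best$par
  vg <- make_variogram(model, p[1], p[1] + p[2], p[3])
  # a curve already at its sill before the first observed distance is
  # indistinguishable from pure nugget; resolve the degeneracy that way
  if (vg$sill > 0 &&
      variogram_semivariance(vg, min(emp$dist)) >= 0.99 * vg$sill) {
    vg <- make_variogram(model, vg$sill, vg$sill, vg$range_m)
  }
  vg
}

# average values at duplicated coordinates (deterministic de-duplication)
merge_duplicates <- function(field) {
  key <- paste(field$x, field$y, sep = "|")
  if (!anyDuplicated(key)) return(field)
  agg <- stats::aggregate(field$value, by = list(key = key), FUN = mean)
  xy <- do.call(rbind, strsplit(agg$key, "|", fixed = TRUE))
  data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]), value = agg$x)
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary kriging system (semivariance matrix bordered by the
#' unit-sum constraint) once and predicts at every target. Weights sum to
#' one; with a zero nugget the prediction at a sample location reproduces
#' the sample value exactly and has zero kriging variance. Duplicate sample
#' coordinates are averaged before solving.
#'
#' @param field data frame with x, y, value.
#' @param vg a fitted `variogram`.
#' @param targets data frame with x, y.
#' @return data frame: x, y, prediction, variance.
#' @export
ok_predict <- function(field, vg, targets) {
  field <- merge_duplicates(field)
  n <- nrow(field)
  if (n < 2L) stop("need at least 2 distinct sample points")
  D <- as.matrix(stats::dist(field[, c("x", "y")]))
  A <- rbind(cbind(variogram_semivariance(vg, D), 1), c(rep(1, n), 0))
  # distances samples x targets
  dx <- outer(field$x, targets$x, "-")
  dy <- outer(field$y, targets$y, "-")
  d0 <- sqrt(dx * dx + dy * dy)
  B <- rbind(variogram_semivariance(vg, d0), 1)
  sol <- tryCatch(solve(A, B), error = function(e) {
    # ridge on the sample block only, keeping the unit-sum constraint exact
    A[seq_len(n), seq_len(n)] <- A[seq_len(n), seq_len(n)] +
      diag(1e-8 * max(vg$sill, 1), n)
    solve(A, B)
  })
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- as.numeric(crossprod(w, field$value))
  var <- pmax(colSums(w * B[seq_len(n), , drop = FALSE]) + mu, 0)
  out <- data.frame(x = targets$x, y = targets$y, prediction = pred,
                    variance = var)
  # samples x targets weight matrix; each column sums to 1
  attr(out, "weights") <- w
  out
}

#' Krige meteorological station values to target locations
#'
#' Fits a per-variable variogram to the met-station samples and predicts at
#' the targets by ordinary kriging. This kriged value is the meteorological
#' predictor the LUR models use.
#'
#' @param met data frame from [generate_meteorology()] (station_id, x, y,
#'   four met variables) or an equivalent real table.
#' @param targets data frame with x, y.
#' @param model variogram family.
#' @param n_bins bins for the empirical variogram.
#' @return data frame aligned with `targets`: one column per met variable.
#' @export
krige_met <- function(met, targets, model = "exponential", n_bins = 10L) {
  out <- data.frame(row.names = seq_len(nrow(targets)))
  for (v in intersect(MET_VARIABLES, names(met))) {
    field <- data.frame(x = met$x, y = met$y, value = met[[v]])
    if (stats::sd(field$value) == 0) {
      out[[v]] <- rep(field$value[1], nrow(targets))
      next
    }
    emp <- empirical_variogram(field, n_bins = n_bins)
    vg <- if (nrow(emp) >= 3L) fit_variogram(emp, model) else
      make_variogram(model, 0, stats::var(field$value), max(emp$dist))
    out[[v]] <- ok_predict(field, vg, targets)$prediction
  }
  out
}
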