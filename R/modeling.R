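# The statistical core: Spearman screening with best-buffer-per-variable
# retention, stepwise multiple linear regression under p < 0.05 and VIF < 5
# constraints, and the sequential partial R-squared decomposition whose
# increments sum exactly to the model R-squared.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Returns NA
#' with a warning when either variable has zero rank variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or NA.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranks; Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Screen predictors: best buffer per base variable
#'
#' For each base variable (e.g. catering across all its radii) only the
#' buffer column with the highest |Spearman rho| against the response is
#' retained; the remaining radii are eliminated to limit within-variable
#' collinearity. Unbuffered variables are retained as themselves. Ties in
#' |rho| go to the smallest radius. Columns with |rho| < `min_abs_rho` (or
#' undefined rho) are excluded entirely.
#'
#' @param matrix a [build_predictor_matrix()] result (rows aligned with y).
#' @param y response vector (missing-response rows already dropped).
#' @param min_abs_rho minimum absolute Spearman correlation to keep a
#'   variable at all (default 0).
#' @return list of class `screen_result`: `retained` (column names) and
#'   `rho` (named vector over all columns).
#' @export
screen_predictors <- function(matrix, y, min_abs_rho = 0) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) stop("empty predictor matrix")
  if (nrow(matrix) != length(y)) stop("matrix rows must align with y")
  cols <- colnames(matrix)
  rho <- vapply(cols, function(cn) {
    v <- matrix[[cn]]
    if (stats::sd(v) == 0 || stats::sd(y) == 0) return(NA_real_)
    suppressWarnings(spearman_rho(v, y))
  }, 0)
  bases <- vapply(cols, function(cn) parse_variable(cn)$base, "")
  radii <- vapply(cols, function(cn) parse_variable(cn)$radius, 0)
  retained <- character(0)
  for (b in unique(bases)) {
    idx <- which(bases == b)
    r <- abs(rho[idx])
    ok <- !is.na(r) & r >= min_abs_rho
    if (!any(ok)) next
    idx <- idx[ok]; r <- r[ok]
    # argmax |rho|; ties -> smallest radius (columns are radius-ascending,
    # but order explicitly to be safe)
    ord <- order(-r, radii[idx])
    retained <- c(retained, cols[idx[ord[1]]])
  }
  structure(list(retained = retained, rho = rho), class = "screen_result")
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) with R2_j from regressing column j on the other
#' columns (with intercept). A single column has VIF 1 by convention;
#' perfectly collinear columns report Inf.
#'
#' @param design numeric matrix or data frame of predictors.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  p <- ncol(X)
  if (p == 0L) return(stats::setNames(numeric(0), character(0)))
  if (p == 1L) return(stats::setNames(1, colnames(X)))
  out <- stats::setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tot <= 0) 1 else 1 - sum(res^2) / tot
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

# fit y ~ X (with intercept); returns coefficients, t, p, r2, sigma
ols_fit <- function(X, y) {
  n <- length(y)
  Xd <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_ <- qr(Xd)
  if (qr_$rank < ncol(Xd)) return(NULL)   # rank-deficient
  coef <- qr.coef(qr_, y)
  res <- y - as.numeric(Xd %*% coef)
  df <- n - ncol(Xd)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(coef = coef, se = se, t = tval, p = pval, rss = rss, tss = tss,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       sigma = sqrt(sigma2), df = df, fitted = as.numeric(Xd %*% coef))
}

#' Sequential partial R-squared decomposition
#'
#' increment_j = R2(first j terms) - R2(first j-1 terms) in entry order;
#' the increments sum to the full-model R2 exactly, which matches how the
#' per-term partial R2 columns of published hourly LUR model tables add up
#' to the printed model R2.
#'
#' @param X data frame / matrix of the selected predictors, columns in
#'   entry order.
#' @param y response.
#' @return named numeric vector of increments.
#' @export
sequential_partial_r2 <- function(X, y) {
  X <- as.data.frame(X)
  p <- ncol(X)
  out <- stats::setNames(numeric(p), colnames(X))
  prev <- 0
  for (j in seq_len(p)) {
    fit <- ols_fit(X[, seq_len(j), drop = FALSE], y)
    if (is.null(fit)) stop("rank-deficient design in partial R2 decomposition")
    out[j] <- fit$r2 - prev
    prev <- fit$r2
  }
  out
}

#' Adjusted R-squared
#'
#' 1 - (1 - r2) (n - 1) / (n - p - 1).
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Root-mean-square error
#' @param observed,predicted aligned numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty input")
  if (length(observed) != length(predicted)) stop("length mismatch")
  sqrt(mean((observed - predicted)^2))
}

#' Stepwise multiple linear regression under p and VIF constraints
#'
#' Forward selection adds, at each step, the candidate with the smallest
#' entry p-value (t-test of its coefficient in the augmented model) if that
#' p-value is below `p_enter`; after each addition a backward pass removes
#' any term whose p-value has risen to `p_remove` or above; finally a VIF
#' pass removes the highest-VIF term while any VIF >= `vif_max` and bars it
#' from re-entry. The loop repeats until no change. Entry stops when the
#' residual sum of squares is numerically zero (perfect fit). If no
#' candidate ever enters, an intercept-only model is returned.
#'
#' @param X data frame of screened candidate predictors.
#' @param y response vector.
#' @param p_enter,p_remove entry/removal significance thresholds.
#' @param vif_max VIF ceiling for retained terms.
#' @return object of class `lur_model`: intercept, terms data frame (name,
#'   coefficient, t, p, vif, partial_r2 in entry order), r2, adjusted_r2,
#'   rmse, n_obs, residual_sd.
#' @export
stepwise_regress <- function(X, y, p_enter = 0.05, p_remove = 0.05,
                             vif_max = 5) {
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) stop("X rows must align with y")
  selected <- character(0)
  barred <- character(0)
  tss <- sum((y - mean(y))^2)
  repeat {
    changed <- FALSE
    # forward step
    candidates <- setdiff(colnames(X), c(selected, barred))
    # keep enough residual df for the t-tests
    if (length(candidates) && n > length(selected) + 3L) {
      cur <- if (length(selected)) ols_fit(X[selected], y) else NULL
      cur_rss <- if (is.null(cur)) tss else cur$rss
      if (cur_rss > max(1e-12 * tss, 0)) {
        entry_p <- vapply(candidates, function(cn) {
          fit <- ols_fit(X[c(selected, cn)], y)
          if (is.null(fit)) return(NA_real_)
          unname(fit$p[cn])
        }, 0)
        entry_p <- entry_p[!is.na(entry_p)]
        if (length(entry_p)) {
          best <- names(entry_p)[order(entry_p, names(entry_p))][1]
          if (entry_p[best] < p_enter) {
            selected <- c(selected, best)
            changed <- TRUE
          }
        }
      }
    }
    # backward pass
    repeat {
      if (length(selected) == 0L) break
      fit <- ols_fit(X[selected], y)
      pv <- fit$p[selected]
      worst <- names(pv)[order(-pv)][1]
      if (pv[worst] >= p_remove) {
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    # VIF pass: remove and bar the highest-VIF offender
    repeat {
      if (length(selected) < 2L) break
      v <- vif(X[selected])
      worst <- names(v)[order(-v)][1]
      if (v[worst] >= vif_max) {
        selected <- setdiff(selected, worst)
        barred <- c(barred, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  build_lur_model(X, y, selected)
}

# assemble the lur_model object for a fixed, ordered term set
build_lur_model <- function(X, y, selected) {
  n <- length(y)
  if (length(selected) == 0L) {
    fit_rmse <- sqrt(mean((y - mean(y))^2))
    out <- list(intercept = mean(y),
                terms = data.frame(name = character(0), coefficient = numeric(0),
                                   t = numeric(0), p = numeric(0),
                                   vif = numeric(0), partial_r2 = numeric(0),
                                   stringsAsFactors = FALSE),
                r2 = 0, adjusted_r2 = 0, rmse = fit_rmse, n_obs = n,
                residual_sd = stats::sd(y))
    class(out) <- "lur_model"
    return(out)
  }
  fit <- ols_fit(X[selected], y)
  vifs <- vif(X[selected])
  partials <- sequential_partial_r2(X[selected], y)
  terms <- data.frame(name = selected,
                      coefficient = unname(fit$coef[selected]),
                      t = unname(fit$t[selected]),
                      p = unname(fit$p[selected]),
                      vif = unname(vifs[selected]),
                      partial_r2 = unname(partials[selected]),
                      stringsAsFactors = FALSE)
  out <- list(intercept = unname(fit$coef["(Intercept)"]), terms = terms,
              r2 = fit$r2,
              adjusted_r2 = adjusted_r2(fit$r2, n, length(selected)),
              rmse = sqrt(fit$rss / n), n_obs = n,
              residual_sd = fit$sigma)
  class(out) <- "lur_model"
  out
}

#' Evaluate the fitted regression equation
#'
#' @param object a `lur_model`.
#' @param newdata data frame containing the model's term columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.lur_model <- function(object, newdata, ...) {
  miss <- setdiff(object$terms$name, colnames(newdata))
  if (length(miss)) stop("newdata lacks model terms: ", paste(miss, collapse = ", "))
  out <- rep(object$intercept, nrow(newdata))
  for (i in seq_len(nrow(object$terms))) {
    out <- out + object$terms$coefficient[i] * newdata[[object$terms$name[i]]]
  }
  out
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> n = %d, R2 = %.3f, adj R2 = %.3f, RMSE = %.2f\n",
              x$n_obs, x$r2, x$adjusted_r2, x$rmse))
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  if (nrow(x$terms)) {
    df <- x$terms
    df$coefficient <- signif(df$coefficient, 4)
    df$t <- round(df$t, 2); df$p <- signif(df$p, 3)
    df$vif <- round(df$vif, 3); df$partial_r2 <- round(df$partial_r2, 3)
    print(df, row.names = FALSE)
  } else cat("  (intercept-only model)\n")
  invisible(x)
}
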