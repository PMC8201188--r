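# Model validation: 10-fold cross-validation with fixed term sets, slot
# descriptive statistics, and normality-gated two-sample slot comparisons.

#' K-fold cross-validation of a fixed term set
#'
#' The selected term set is held fixed (selection is not re-run per fold,
#' matching the presentation of one final model per slot with accompanying
#' CV metrics); only the coefficients are refit on each training 9/10 and
#' scored on the held-out tenth. Fold sizes differ by at most one. Pooled
#' CV R2 is 1 - SSE_heldout/SST over all held-out predictions jointly, then
#' adjusted with the full n and the model's p. Set `reselect = TRUE` to
#' re-run the full screening + stepwise selection inside every fold (the
#' stricter, honest-CV variant).
#'
#' @param X data frame of the selected predictors (or, with `reselect`,
#'   the full screened candidate set).
#' @param y response vector.
#' @param k number of folds.
#' @param seed integer seed for the random partition.
#' @param reselect re-run stepwise selection within each fold.
#' @param ... passed to [stepwise_regress()] when `reselect = TRUE`.
#' @return list of class `cv_report`: fold_assignments, per-fold metrics,
#'   cv_r2, cv_adjusted_r2, cv_rmse, seed.
#' @export
kfold_cv <- function(X, y, k = 10L, seed = 1L, reselect = FALSE, ...) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n < k) stop("need at least k observations for k-fold CV")
  folds <- with_seed(seed, {
    sizes <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
    sample(rep(seq_len(k), times = sizes))
  })
  held_pred <- numeric(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (reselect) {
      m <- stepwise_regress(X[tr, , drop = FALSE], y[tr], ...)
      terms <- m$terms$name
      pred <- predict(m, X[!tr, , drop = FALSE])
      ptr <- predict(m, X[tr, , drop = FALSE])
    } else {
      # plain coefficient refit; aliased columns (degenerate within a
      # fold) drop out with a zero coefficient
      terms <- colnames(X)
      Xtr <- cbind(1, as.matrix(X[tr, , drop = FALSE]))
      beta <- stats::lm.fit(Xtr, y[tr])$coefficients
      beta[is.na(beta)] <- 0
      pred <- as.numeric(cbind(1, as.matrix(X[!tr, , drop = FALSE])) %*% beta)
      ptr <- as.numeric(Xtr %*% beta)
    }
    held_pred[!tr] <- pred
    tr_r2 <- 1 - sum((y[tr] - ptr)^2) / sum((y[tr] - mean(y[tr]))^2)
    per_fold[[f]] <- data.frame(
      fold = f, n_train = sum(tr), n_test = sum(!tr),
      train_adjusted_r2 = if (sum(tr) > length(terms) + 1)
        adjusted_r2(tr_r2, sum(tr), length(terms)) else NA_real_,
      test_rmse = rmse(y[!tr], pred))
  }
  sse <- sum((y - held_pred)^2)
  sst <- sum((y - mean(y))^2)
  cv_r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  p <- ncol(X)
  out <- list(fold_assignments = folds, per_fold = do.call(rbind, per_fold),
              cv_r2 = cv_r2,
              cv_adjusted_r2 = if (!is.na(cv_r2) && n > p + 1)
                adjusted_r2(cv_r2, n, p) else NA_real_,
              cv_rmse = sqrt(sse / n), seed = seed, heldout = held_pred)
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds: cv R2 %.3f, cv adj R2 %.3f, cv RMSE %.3f\n",
              nrow(x$per_fold), x$cv_r2, x$cv_adjusted_r2, x$cv_rmse))
  invisible(x)
}

#' Descriptive summary of one slot's observations
#'
#' Mean, SD, max, min, median and the interquartile bounds, with quantiles
#' by linear interpolation between order statistics.
#'
#' @param x numeric vector of concentrations (NA removed).
#' @return list of class `slot_summary`.
#' @export
slot_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no observations")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- list(n = length(x), mean = mean(x), sd = stats::sd(x),
              max = max(x), min = min(x), median = q[2],
              iqr_low = q[1], iqr_high = q[3])
  class(out) <- "slot_summary"
  out
}

#' @export
print.slot_summary <- function(x, ...) {
  cat(sprintf("n=%d mean=%.1f sd=%.1f min=%.1f IQR=[%.1f, %.1f] median=%.1f max=%.1f\n",
              x$n, x$mean, x$sd, x$min, x$iqr_low, x$iqr_high, x$median, x$max))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, n >= 3, not constant.
#' @return list(statistic, p).
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant sample: normality test degenerate")
  if (length(x) > 5000L) x <- x[seq_len(5000L)]
  ht <- stats::shapiro.test(x)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Compare the concentrations of two slots
#'
#' Routing follows the distribution shape: if both samples pass the
#' Shapiro-Wilk normality test at `alpha`, a two-sample t-test is used
#' (Welch by default; `pooled = TRUE` for the classical equal-variance
#' Student test); otherwise a two-sided Mann-Whitney U test.
#'
#' @param a,b numeric samples (each n >= 3).
#' @param alpha significance level for both the normality gate and the
#'   reported `significant` flag.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return list: test_used ("t_test" or "mann_whitney"), statistic, p,
#'   significant.
#' @export
compare_slots <- function(a, b, alpha = 0.05, pooled = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) stop("each sample needs n >= 3")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("degenerate samples")
  normal <- stats::sd(a) > 0 && stats::sd(b) > 0 &&
    normality_test(a)$p > alpha && normality_test(b)$p > alpha
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = pooled)
    test_used <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test_used <- "mann_whitney"
  }
  list(test_used = test_used, statistic = unname(ht$statistic),
       p = ht$p.value, significant = ht$p.value < alpha)
}
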