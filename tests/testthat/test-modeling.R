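# Screening, VIF, stepwise selection and the fit diagnostics.

test_that("spearman_rho matches the mid-rank Pearson oracle", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  x <- c(1, 2, 2, 4); y <- c(10, 20, 30, 40)
  oracle <- cor(rank(x), rank(y))            # mid-rank Pearson
  expect_equal(spearman_rho(x, y), oracle)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
})

test_that("screening keeps the best buffer per base variable", {
  set.seed(5)
  n <- 40
  y <- rnorm(n)
  X <- data.frame(catering_300 = y + rnorm(n, 0, 2),
                  catering_500 = y + rnorm(n, 0, 0.2),
                  catering_900 = y + rnorm(n, 0, 1),
                  elevation = rnorm(n))
  sc <- screen_predictors(X, y)
  expect_true("catering_500" %in% sc$retained)
  expect_identical(sum(grepl("^catering", sc$retained)), 1L)
  expect_true("elevation" %in% sc$retained)

  # |rho| tie goes to the smallest radius
  X2 <- data.frame(catering_300 = 1:10, catering_500 = (1:10) * 2)
  sc2 <- screen_predictors(X2, 1:10 + 0)
  expect_identical(sc2$retained, "catering_300")

  # min_abs_rho excludes weak variables entirely
  sc3 <- screen_predictors(X, y, min_abs_rho = 0.99)
  expect_false("elevation" %in% sc3$retained)
  expect_error(screen_predictors(X[0, ], numeric(0)), "empty")
})

test_that("VIF matches its closed form and flags exact collinearity", {
  set.seed(8)
  # principal-component scores: centered and mutually orthogonal
  X <- prcomp(matrix(rnorm(100), 20, 5))$x
  expect_equal(unname(vif(X)), rep(1, 5), tolerance = 1e-9)

  # two columns with sample correlation exactly 0.9
  a <- scale(rnorm(50))[, 1]
  b <- scale(resid(lm(rnorm(50) ~ a)))[, 1]
  x2 <- 0.9 * a + sqrt(1 - 0.81) * b
  V <- vif(cbind(a = a, x2 = x2))
  expect_equal(unname(V), rep(1 / (1 - 0.81), 2), tolerance = 1e-3)

  dup <- cbind(a = a, b = a)
  expect_true(all(is.infinite(vif(dup))))
  expect_equal(unname(vif(cbind(a = a))), 1)
})

test_that("stepwise recovers a noiseless single-predictor model exactly", {
  set.seed(2)
  x1 <- rnorm(50); x2 <- rnorm(50)
  y <- 3 + 2 * x1
  m <- stepwise_regress(data.frame(x1 = x1, x2 = x2), y)
  expect_identical(m$terms$name, "x1")
  expect_equal(m$terms$coefficient, 2, tolerance = 1e-8)
  expect_equal(m$intercept, 3, tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-9)
})

test_that("constant response yields an intercept-only model", {
  set.seed(3)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  m <- stepwise_regress(X, rep(5, 30))
  expect_identical(nrow(m$terms), 0L)
  expect_equal(m$intercept, 5)
})

test_that("a duplicated informative column enters only once", {
  set.seed(9)
  x <- rnorm(60)
  y <- 1 + 4 * x + rnorm(60, 0, 0.5)
  m <- stepwise_regress(data.frame(a = x, b = x, c = rnorm(60)), y)
  expect_identical(sum(m$terms$name %in% c("a", "b")), 1L)
})

test_that("fitted models honour the p and VIF constraints post hoc", {
  set.seed(11)
  n <- 80
  X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  colnames(X) <- paste0("v", 1:10)
  X$v2 <- X$v1 + rnorm(n, 0, 0.1)            # near-collinear pair
  y <- 2 + 3 * X$v1 - 2 * X$v5 + rnorm(n)
  m <- stepwise_regress(X, y)
  expect_true(all(m$terms$p < 0.05))
  expect_true(all(m$terms$vif < 5))
  expect_true(abs(sum(m$terms$partial_r2) - m$r2) <= 1e-9)
})

test_that("sequential partial R2 sums to the model R2", {
  set.seed(21)
  n <- 50
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1 + X$a + 0.5 * X$b + rnorm(n)
  inc <- sequential_partial_r2(X, y)
  full <- summary(lm(y ~ ., X))$r.squared
  expect_equal(sum(inc), full, tolerance = 1e-12)
  # single term: increment equals the model R2
  inc1 <- sequential_partial_r2(X["a"], y)
  expect_equal(unname(inc1), summary(lm(y ~ a, X))$r.squared)
})

test_that("orthogonal predictors decompose additively in any order", {
  set.seed(22)
  # principal-component scores are centered and orthogonal, so marginal
  # R2 contributions add exactly in any entry order
  X <- as.data.frame(prcomp(matrix(rnorm(40 * 3), 40, 3))$x)
  colnames(X) <- c("a", "b", "c")
  y <- 2 * X$a - 1 * X$b + 0.5 * X$c
  inc_abc <- sequential_partial_r2(X[c("a", "b", "c")], y)
  inc_cba <- sequential_partial_r2(X[c("c", "b", "a")], y)
  marg <- vapply(c("a", "b", "c"), function(v)
    summary(lm(y ~ X[[v]]))$r.squared, 0)
  expect_equal(unname(inc_abc[c("a", "b", "c")]), unname(marg), tolerance = 1e-9)
  expect_equal(unname(inc_cba[c("a", "b", "c")]), unname(marg), tolerance = 1e-9)
})

test_that("adjusted R2 follows its closed form", {
  expect_equal(adjusted_r2(1, 35, 3), 1)
  expect_equal(adjusted_r2(0.5, 35, 2), 0.46875)
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
})

test_that("rmse follows its definition and is permutation invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(1)
  o <- rnorm(20); p <- rnorm(20); perm <- sample(20)
  expect_equal(rmse(o, p), rmse(o[perm], p[perm]))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("refitting a subset never beats the full selected model", {
  set.seed(33)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1 + X$a + X$b + rnorm(n, 0, 0.5)
  m <- stepwise_regress(X, y)
  full_r2 <- m$r2
  for (k in seq_len(nrow(m$terms))) {
    sub <- m$terms$name[-k]
    r2 <- if (length(sub)) summary(lm(y ~ ., X[sub]))$r.squared else 0
    expect_lte(r2, full_r2 + 1e-12)
  }
})

test_that("predict.lur_model evaluates the regression equation", {
  set.seed(44)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- 2 + 3 * X$a + rnorm(30, 0, 0.1)
  m <- stepwise_regress(X, y)
  newd <- data.frame(a = c(0, 1), b = c(5, 5))
  expect_equal(predict(m, newd),
               m$intercept + m$terms$coefficient[1] * c(0, 1))
  expect_error(predict(m, data.frame(z = 1)), "lacks model terms")
})
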