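test_that("KRR dual solve matches a dense-solver oracle", {
  x <- with_fixed_seed(10, matrix(rnorm(6 * 15), 6, 15))
  y <- with_fixed_seed(11, rnorm(6))
  lam <- 0.7
  m <- krr(x, y, lambda = lam)
  k <- correlation_kernel(x)
  alpha_oracle <- solve(k + lam * diag(6), y - mean(y))
  expect_equal(m$alpha, alpha_oracle, tolerance = 1e-8)
  xnew <- with_fixed_seed(12, matrix(rnorm(3 * 15), 3, 15))
  pred_oracle <- drop(correlation_kernel(xnew, x) %*% alpha_oracle) + mean(y)
  expect_equal(predict(m, xnew), pred_oracle, tolerance = 1e-8)
  expect_lt(m$dual_residual, 1e-6)
})

test_that("KRR limits behave: identity kernel, strong shrinkage, interpolation", {
  y <- c(-2, -1, 0, 1, 2)  # zero mean, so centering changes nothing
  f <- fit_krr(diag(5), y, lambda = 1)
  expect_equal(f$alpha, y / 2, tolerance = 1e-12)

  x <- with_fixed_seed(13, matrix(rnorm(8 * 20), 8, 20))
  yr <- with_fixed_seed(14, rnorm(8, mean = 5))
  m_inf <- krr(x, yr, lambda = 1e12)
  expect_equal(predict(m_inf, x), rep(mean(yr), 8), tolerance = 1e-6)
  expect_lt(sqrt(sum(m_inf$alpha^2)), 1e-9)

  # full-rank kernel at lambda = 0 interpolates the training targets
  m0 <- krr(x, yr, lambda = 0)
  expect_equal(predict(m0, x), yr, tolerance = 1e-6)

  # constant targets give constant predictions
  mc <- krr(x, rep(3, 8), lambda = 1)
  expect_equal(predict(mc, x), rep(3, 8), tolerance = 1e-10)
})

test_that("KRR predictions are invariant to per-participant affine rescaling", {
  x <- with_fixed_seed(15, matrix(rnorm(12 * 25), 12, 25))
  y <- with_fixed_seed(16, rnorm(12))
  scale_r <- with_fixed_seed(17, runif(12, 0.5, 2))
  shift_r <- with_fixed_seed(18, rnorm(12))
  x2 <- x * scale_r + shift_r
  m1 <- krr(x, y, lambda = 0.5)
  m2 <- krr(x2, y, lambda = 0.5)
  xnew <- with_fixed_seed(19, matrix(rnorm(4 * 25), 4, 25))
  expect_equal(predict(m1, xnew), predict(m2, xnew), tolerance = 1e-10)
})

test_that("lambda tuning: grids, ties and the noiseless-fit oracle", {
  x <- with_fixed_seed(20, matrix(rnorm(30 * 10), 30, 10))
  # noiseless target from one training participant's kernel row: the
  # smallest grid lambda fits it best
  k <- correlation_kernel(x)
  y <- k[, 7]
  m <- krr(x, y, lambda_grid = c(1e-4, 1, 100), seed = 2)
  expect_equal(m$lambda, 1e-4)
  expect_equal(nrow(m$cv), 3L)

  # a single-lambda grid is chosen as-is
  m1 <- krr(x, y, lambda_grid = 3.3, seed = 2)
  expect_equal(m1$lambda, 3.3)

  # exact tie in CV score resolves to the largest lambda
  expect_equal(metamatchr:::pick_lambda(c(1, 2, 4), c(0.5, 0.2, 0.2)), 4)

  # CV determinism: same seed, same folds, same choice
  ya <- with_fixed_seed(21, y + rnorm(30, sd = 0.5))
  ma <- krr(x, ya, lambda_grid = fast_grid, seed = 9)
  mb <- krr(x, ya, lambda_grid = fast_grid, seed = 9)
  expect_identical(ma$lambda, mb$lambda)
  expect_identical(ma$cv, mb$cv)
  expect_error(krr(x[1:4, ], ya[1:4], lambda_grid = fast_grid, n_folds = 5),
               "5-fold")
})

test_that("LRR matches the normal-equations oracle and its limits", {
  x <- with_fixed_seed(22, matrix(rnorm(50 * 10), 50, 10))
  w_true <- with_fixed_seed(23, rnorm(10))
  y <- drop(x %*% w_true) + with_fixed_seed(24, rnorm(50, sd = 0.3))
  lam <- 2.5
  m <- lrr(x, y, lambda = lam)
  xc <- sweep(x, 2, colMeans(x)); yc <- y - mean(y)
  w_oracle <- solve(crossprod(xc) + lam * diag(10), crossprod(xc, yc))
  expect_equal(m$weights, drop(w_oracle), tolerance = 1e-8)
  expect_equal(m$intercept, mean(y) - sum(colMeans(x) * w_oracle),
               tolerance = 1e-8)

  # univariate noiseless slope
  x1 <- matrix(seq(-2, 2, length.out = 20), ncol = 1)
  m1 <- lrr(x1, drop(2 * x1), lambda = 1e-10)
  expect_equal(m1$weights, 2, tolerance = 1e-6, ignore_attr = TRUE)

  # strong shrinkage: weights to 0, intercept to mean(y)
  minf <- lrr(x, y, lambda = 1e12)
  expect_lt(max(abs(minf$weights)), 1e-8)
  expect_equal(minf$intercept, mean(y), tolerance = 1e-6)

  # wide problem (d > n) takes the dual path; check against primal algebra
  xw <- with_fixed_seed(25, matrix(rnorm(15 * 40), 15, 40))
  yw <- with_fixed_seed(26, rnorm(15))
  mw <- lrr(xw, yw, lambda = 1.2)
  xwc <- sweep(xw, 2, colMeans(xw))
  w_or <- solve(crossprod(xwc) + 1.2 * diag(40), crossprod(xwc, yw - mean(yw)))
  expect_equal(mw$weights, drop(w_or), tolerance = 1e-7)

  expect_error(lrr(x, rep(NA_real_, 50)), "missing")
})

test_that("missing targets are excluded, and extra missing rows change nothing", {
  x <- with_fixed_seed(27, matrix(rnorm(40 * 8), 40, 8))
  y <- with_fixed_seed(28, rnorm(40))
  y_na <- c(y, NA, NA)
  x_ext <- rbind(x, matrix(999, 2, 8))
  m_l1 <- lrr(x, y, lambda_grid = fast_grid, seed = 4)
  m_l2 <- lrr(x_ext, y_na, lambda_grid = fast_grid, seed = 4)
  expect_identical(m_l1$weights, m_l2$weights)
  m_k1 <- krr(x, y, lambda_grid = fast_grid, seed = 4)
  m_k2 <- krr(x_ext, y_na, lambda_grid = fast_grid, seed = 4)
  expect_identical(m_k1$alpha, m_k2$alpha)
})

test_that("correlation-kernel KRR equals primal ridge on normalized features", {
  x <- with_fixed_seed(29, matrix(rnorm(20 * 12, mean = 1), 20, 12))
  y <- with_fixed_seed(30, rnorm(20))
  xn <- normalize_features(x)
  lam <- 0.8
  m <- krr(x, y, lambda = lam)
  # primal ridge on the normalized rows with matched centering
  w <- solve(crossprod(xn) + lam * diag(12), crossprod(xn, y - mean(y)))
  xnew <- with_fixed_seed(31, matrix(rnorm(5 * 12), 5, 12))
  xnn <- normalize_features(xnew)
  expect_equal(predict(m, xnew), drop(xnn %*% w) + mean(y), tolerance = 1e-6)
})
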