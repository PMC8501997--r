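test_that("the log/centre/scale transform has the stated properties", {
  set.seed(41)
  X <- matrix(rexp(60 * 4, 1 / 5), 60, 4)
  tx <- transform_features(X)
  expect_equal(unname(colMeans(tx$X)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(tx$X, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # a zero column becomes constant under log1p and is dropped with a warning
  expect_warning(tz <- transform_features(cbind(X, 0)), "constant")
  expect_equal(tz$kept, 1:4)
  expect_error(transform_features(matrix(c(-1, 2), 1, 2)), "negative")
  # train-estimated parameters applied to new data reproduce the train map
  tx2 <- transform_features(X, center = tx$center, scale = tx$scale)
  expect_equal(tx2$X, tx$X)
})

test_that("a noise-free linear driver is recovered with high held-out correlation", {
  set.seed(42)
  m <- 60
  X <- cbind(rexp(m, 1 / 10), matrix(rexp(m * 10, 1 / 10), m, 10))
  y <- exp(scale(log1p(X[, 1]))[, 1] + 3) - 1   # y = monotone map of column 1
  cfg <- reg_config(alpha_grid = seq(0, 1, 0.25), seed = 5)
  en <- fit_elastic_net_mc_cv(X, y, cfg)
  expect_gt(en$median_coefficients[1], 0)
  expect_gte(en$mean_test_rho, 0.99)
  expect_equal(median_nonzero(en)[1], 1L)
})

test_that("independent expression yields no significant model", {
  set.seed(43)
  null_p <- vapply(1:10, function(s) {
    m <- 60
    X <- matrix(rexp(m * 6, 1 / 5), m, 6)
    y <- rexp(m, 1 / 5)
    en <- fit_elastic_net_mc_cv(X, y, reg_config(alpha_grid = c(0, 0.5, 1),
                                                 seed = s))
    c(en$mean_test_r, en$model_p)
  }, numeric(2))
  # across seeds the held-out correlation is centred near zero and the
  # pooled-correlation p-value is almost never significant
  expect_lte(abs(mean(null_p[1, ], na.rm = TRUE)), 0.3)
  expect_gte(sum(null_p[2, ] > 0.05), 9)
})

test_that("the printed alpha = 1 endpoint matches the ridge closed form", {
  # printed alpha = 1 -> pure squared penalty; on standardized X with a fixed
  # lambda, glmnet's ridge solves (X'X + m lambda I) b = X'y
  set.seed(44)
  m <- 50; p <- 4
  X <- scale(matrix(rnorm(m * p), m, p))
  X <- sweep(X, 2, apply(X, 2, function(c) sqrt(sum(c^2) / m)), "/")
  y <- as.numeric(scale(X %*% c(1, -0.5, 0.25, 0) + rnorm(m, 0, 0.3)))
  lam <- 0.7
  fit <- glmnet::glmnet(X, y, alpha = 0, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
  # glmnet works on y scaled by its population SD, so the effective ridge
  # penalty on the original scale is m * lambda / sd_pop(y)
  sy <- sqrt(mean((y - mean(y))^2))
  closed <- solve(crossprod(X) + m * lam / sy * diag(p), crossprod(X, y))
  expect_equal(as.numeric(fit$beta), as.numeric(closed), tolerance = 1e-6)
})

test_that("BY q-values match p.adjust and an example evaluates exactly", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  q <- by_correction(p)
  # c(5) = 1 + 1/2 + ... + 1/5 = 2.2833; all five share q = 0.05*5*c(5)/5
  expect_equal(q, rep(0.05 * 5 * sum(1 / (1:5)) / 5, 5), tolerance = 1e-12)
  expect_equal(by_correction(0.03), 0.03)
  expect_equal(by_correction(rep(1, 7)), rep(1, 7))
})

test_that("OLS reproduces the normal equations and flags collinearity", {
  set.seed(45)
  m <- 40
  X <- matrix(rexp(m * 3, 1 / 8), m, 3)
  b_true <- c(0.9, -0.6, 0.3)
  ylog <- as.numeric(scale(log1p(X)) %*% b_true) + 6  # keep exp(.) - 1 > 0
  y <- exp(ylog) - 1
  # noise-free by construction: lm's perfect-fit warning is expected
  ols <- suppressWarnings(fit_ols(X, y))
  # normal-equations oracle on the same transformed design
  Xs <- scale(log1p(X)); ys <- as.numeric(scale(log1p(y)))
  Xd <- cbind(1, Xs)
  beta_ne <- solve(crossprod(Xd), crossprod(Xd, ys))[-1]
  expect_equal(unname(ols$coefficients), unname(beta_ne), tolerance = 1e-8)
  expect_true(all(ols$pvalues < 1e-6))
  # a duplicated column is pruned, not fatal
  ols2 <- suppressWarnings(fit_ols(cbind(X, X[, 1]), y))
  expect_true(4 %in% ols2$dropped)
  expect_equal(unname(ols2$coefficients[1:3]), unname(beta_ne),
               tolerance = 1e-6)
})

test_that("identical seeds reproduce folds and coefficients exactly", {
  set.seed(46)
  m <- 30
  X <- matrix(rexp(m * 5, 1 / 6), m, 5)
  y <- rexp(m, 1 / 4)
  cfg <- reg_config(alpha_grid = c(0, 0.5, 1), seed = 11)
  a <- fit_elastic_net_mc_cv(X, y, cfg)
  b <- fit_elastic_net_mc_cv(X, y, cfg)
  expect_identical(a$folds, b$folds)
  expect_identical(a$coefficients, b$coefficients)
})

test_that("scaling raw expression leaves the selected features unchanged", {
  set.seed(47)
  m <- 50
  X <- cbind(rexp(m, 1 / 10), matrix(rexp(m * 6, 1 / 10), m, 6))
  y <- exp(2 + scale(log1p(X[, 1]))[, 1] * 0.8 + rnorm(m, 0, 0.3)) - 1
  cfg <- reg_config(alpha_grid = c(0, 0.5, 1), seed = 3)
  s1 <- median_nonzero(fit_elastic_net_mc_cv(X, y, cfg))
  s2 <- median_nonzero(fit_elastic_net_mc_cv(X, 100 * y, cfg))
  # log then standardize makes a y rescaling near-shift-like; the strong
  # driver must stay selected either way
  expect_true(1 %in% s1 && 1 %in% s2)
})

test_that("BY is elementwise at least as conservative as BH", {
  set.seed(48)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_true(all(by_correction(p) >= p.adjust(p, "BH") - 1e-15))
  }
})
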