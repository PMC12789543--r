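test_that("a constant response is reproduced exactly with vanishing sigma", {
  set.seed(61)
  X <- matrix(runif(300), 100, 3)
  fit <- bart(X, rep(3.7, 100), m = 20, n_burn = 100, n_draws = 50,
              n_chains = 2)
  expect_lt(max(abs(predict(fit, X, type = "mean") - 3.7)), 1e-6)
  expect_lt(mean(fit$sigma), 1e-6)
})

test_that("a hand-built single-split forest is evaluated exactly", {
  # root splits on feature 1 at 0.5; left leaf -1, right leaf +2
  tree <- matrix(c(
    1, 0.5, 2, 3, 0, 0,
    0, 0,   0, 0, -1, 1,
    0, 0,   0, 0,  2, 1
  ), nrow = 3, byrow = TRUE)
  fake <- structure(list(
    forests = list(list(tree)), sigma = 0.1, m = 1, n_draws = 1,
    features = "x1", y_centre = 0, y_scale = 1
  ), class = "bart")
  p <- predict(fake, data.frame(x1 = c(0.3, 0.5, 0.9)), type = "draws")
  expect_equal(as.numeric(p), c(-1, -1, 2))  # boundary goes left (<=)
})

test_that("posterior summaries use linear-interpolation percentiles", {
  s <- posterior_summary(matrix(1:200, nrow = 1))
  expect_equal(s$mean, 100.5)
  expect_equal(s$p5, 10.95)
  expect_equal(s$p95, 190.05)

  # identical draws collapse the interval; permutation leaves it unchanged
  s2 <- posterior_summary(matrix(7, 3, 10))
  expect_true(all(s2$mean == 7 & s2$p5 == 7 & s2$p95 == 7))
  set.seed(62)
  d <- matrix(rnorm(500), 5, 100)
  expect_equal(posterior_summary(d), posterior_summary(d[, sample(100)]))
  expect_error(posterior_summary(matrix(1, 2, 1)), "at least 2")
})

test_that("fits are deterministic for a fixed seed and config", {
  set.seed(63)
  X <- matrix(runif(300), 100, 3)
  y <- X[, 1] + rnorm(100, 0, 0.2)
  f1 <- bart(X, y, m = 10, n_burn = 50, n_draws = 20, n_chains = 2, seed = 4)
  f2 <- bart(X, y, m = 10, n_burn = 50, n_draws = 20, n_chains = 2, seed = 4)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("fits are equivariant under affine response transforms", {
  set.seed(64)
  X <- matrix(runif(300), 100, 3)
  y <- 2 * X[, 1] + rnorm(100, 0, 0.2)
  f1 <- bart(X, y, m = 10, n_burn = 50, n_draws = 30, n_chains = 2, seed = 5)
  f2 <- bart(X, 10 * y + 3, m = 10, n_burn = 50, n_draws = 30, n_chains = 2,
             seed = 5)
  # internal rescaling makes the sampler see identical problems
  expect_equal(predict(f2, X), 10 * predict(f1, X) + 3, tolerance = 1e-8)
})

test_that("Friedman benchmark: more trees never hurt, intervals calibrated", {
  set.seed(65)
  n <- 300; p <- 8
  X <- matrix(runif(n * p), n, p)
  f <- function(X) 10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 +
    10 * X[, 4] + 5 * X[, 5]
  y <- f(X) + rnorm(n)
  Xt <- matrix(runif(n * p), n, p)
  yt <- f(Xt) + rnorm(n)

  rmse <- function(m) {
    fit <- bart(X, y, m = m, n_burn = 300, n_draws = 100, n_chains = 2,
                seed = 6)
    sqrt(mean((predict(fit, Xt, type = "mean") - yt)^2))
  }
  r1 <- rmse(1)
  r25 <- rmse(25)
  expect_lt(r25, r1 * 1.05)

  fit <- bart(X, y, m = 25, n_burn = 300, n_draws = 200, n_chains = 2,
              seed = 7)
  ppd <- predict(fit, Xt, type = "ppd")
  qs <- t(apply(ppd, 1, quantile, c(0.05, 0.95)))
  cover <- mean(yt >= qs[, 1] & yt <= qs[, 2])
  expect_gte(cover, 0.80)
  expect_lte(cover, 0.97)
})

test_that("input contracts are enforced", {
  X <- matrix(runif(60), 20, 3)
  expect_error(bart(X, rnorm(20)), "at least 50")
  X2 <- matrix(runif(300), 100, 3)
  y <- rnorm(100)
  X2[3, 2] <- NA
  expect_error(bart(X2, y), "missing values")

  set.seed(66)
  fit <- bart(matrix(runif(300), 100, 3), rnorm(100), m = 5, n_burn = 20,
              n_draws = 10, n_chains = 2)
  expect_error(predict(fit, data.frame(a = 1)), "missing training features")
  expect_identical(nrow(predict(fit, matrix(numeric(0), 0, 3))), 0L)
  # constant feature columns are legal and never split on
  Xc <- cbind(matrix(runif(200), 100, 2), 1)
  expect_s3_class(bart(Xc, rnorm(100), m = 5, n_burn = 20, n_draws = 10,
                       n_chains = 2), "bart")
})

test_that("formula interface and methods behave like a classic model fit", {
  set.seed(67)
  df <- data.frame(a = runif(100), b = runif(100))
  df$y <- 2 * df$a + rnorm(100, 0, 0.1)
  fit <- bart(y ~ a + b, df, m = 10, n_burn = 100, n_draws = 50,
              n_chains = 2, seed = 1)
  expect_s3_class(fit, "bart")
  expect_length(fitted(fit), 100)
  expect_equal(fitted(fit) + residuals(fit), df$y, tolerance = 1e-12)
  expect_output(print(fit), "sum of 10 trees")
  expect_output(print(summary(fit)), "in-sample RMSE")
  expect_gt(summary(fit)$train_r2, 0.8)
})
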