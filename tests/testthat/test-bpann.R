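test_that("data splitting follows largest-remainder rounding and is seeded", {
  s160 <- split_data(160, seed = 1)
  expect_equal(lengths(s160), c(train = 96L, val = 24L, test = 40L))
  s8 <- split_data(8, seed = 1)
  expect_equal(lengths(s8), c(train = 5L, val = 1L, test = 2L))
  expect_equal(sort(unname(unlist(s160))), 1:160)  # disjoint, exhaustive
  expect_identical(split_data(50, seed = 3), split_data(50, seed = 3))
  expect_false(identical(split_data(50, seed = 3), split_data(50, seed = 4)))
  expect_error(split_data(5), "at least 8")
  expect_error(split_data(100, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("regression metrics match hand values and a textbook oracle", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$R2, 1)
  expect_equal(m$RMSE, 0)
  expect_equal(m$RAD_avg, 0)
  m2 <- regression_metrics(c(100, 100), c(90, 110))
  expect_equal(m2$RMSE, 10)
  expect_equal(m2$RAD_avg, 10)
  # zero-variance truth flags undefined R2
  m3 <- regression_metrics(c(5, 5, 5), c(4, 5, 6))
  expect_false(m3$r2_defined)
  expect_true(is.na(m3$R2))
  set.seed(12)
  for (k in 1:10) {
    yt <- runif(30, 10, 100); yp <- yt + rnorm(30, 0, 5)
    m <- regression_metrics(yt, yp)
    expect_equal(m$R2, 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2),
                 tolerance = 1e-12)
    expect_equal(m$RMSE, sqrt(mean((yt - yp)^2)), tolerance = 1e-12)
    expect_equal(m$RAD_avg, mean(abs(yp - yt) / yt * 100), tolerance = 1e-12)
    expect_equal(m$RAD_max, max(abs(yp - yt) / yt * 100), tolerance = 1e-12)
  }
  expect_error(regression_metrics(1:3, 1:2), "equal length")
})

test_that("the hidden-size rule and validation search behave as documented", {
  set.seed(5)
  X <- matrix(rnorm(120 * 110), 120, 110)
  y <- as.numeric(X %*% rnorm(110))
  m <- bpann_train(X, y, a = 3, max_epochs = 3, seed = 1)
  expect_equal(m$h, ceiling(sqrt(111)) + 3)   # 14
  expect_equal(m$a, 3L)
  expect_error(bpann_train(X, y, a = 11), "1-10")
  expect_error(bpann_train(X, cbind(y, y)[, 1][-1]), "nrow")
  expect_error(bpann_train(matrix(1, 20, 3), rnorm(20)), "varying")
})

test_that("an LM-trained net reaches R2 >= 0.99 on a noiseless linear target", {
  set.seed(99)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- as.numeric(X %*% c(2, -1, 0.5, 3, -2) + 10)
  # capacity above the interpolation threshold, no weight decay: the LM
  # optimizer itself must recover the linear map
  m <- bpann_train(X, y, hidden = 30, regularization = 0, max_epochs = 400,
                   patience = 50, seed = 2)
  yh <- predict(m, X[m$split$test, , drop = FALSE])
  expect_gte(regression_metrics(y[m$split$test], yh)$R2, 0.99)
})

test_that("a constant target trains to a constant prediction", {
  set.seed(1)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(7, 40)
  m <- bpann_train(X, y, a = 1, seed = 1)
  yh <- predict(m, X)
  expect_lt(sqrt(mean((yh - 7)^2)), 1e-6)
})

test_that("prediction is a deterministic forward pass with stored scaling", {
  set.seed(2)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- as.numeric(X %*% c(1, 2, 3, 4)) + rnorm(60, 0, 0.1)
  m <- bpann_train(X, y, a = 2, seed = 3)
  expect_identical(predict(m, X), predict(m, X))
  expect_error(predict(m, X[, 1:3]), "does not match")
  # zero-weight model predicts the (de-standardized) output bias everywhere
  m0 <- m
  m0$theta[] <- 0
  expect_equal(unname(predict(m0, X)), rep(m$y_center, 60))
  # a tiny overfit net reproduces its training rows
  X5 <- matrix(rnorm(10 * 2), 10, 2)
  y5 <- as.numeric(X5 %*% c(2, -3))
  m5 <- bpann_train(X5, y5, hidden = 8, regularization = 0,
                    split = c(0.8, 0.1, 0.1), max_epochs = 400, seed = 4)
  expect_gt(regression_metrics(y5, predict(m5, X5))$R2, 0.999)
})

test_that("training is seeded-deterministic and leak-free", {
  set.seed(6)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- as.numeric(X %*% rnorm(6)) + rnorm(80, 0, 0.2)
  m1 <- bpann_train(X, y, a = 2, seed = 11)
  m2 <- bpann_train(X, y, a = 2, seed = 11)
  expect_identical(m1$theta, m2$theta)
  # permuting test-set labels must not change the fitted weights or scaling
  y_perm <- y
  y_perm[m1$split$test] <- sample(y[m1$split$test])
  m3 <- bpann_train(X, y_perm, a = 2, seed = 11)
  expect_identical(m1$theta, m3$theta)
  expect_identical(m1$center, m3$center)
  # standardization comes from the training split only
  expect_equal(unname(m1$center),
               unname(colMeans(X[m1$split$train, , drop = FALSE])))
})

test_that("the adam backend also fits a simple target", {
  set.seed(7)
  X <- matrix(rnorm(150 * 3), 150, 3)
  y <- as.numeric(X %*% c(1, -2, 0.5))
  m <- bpann_train(X, y, a = 2, optimizer = "adam", max_epochs = 2000,
                   patience = 2000, seed = 1)
  yh <- predict(m, X[m$split$test, , drop = FALSE])
  expect_gte(regression_metrics(y[m$split$test], yh)$R2, 0.9)
})
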