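test_that("hidden-layer sizing follows the square-root rule with round-half-up", {
  expect_equal(unname(sizing_range(14, 1)), c(5, 14))
  expect_equal(unname(sizing_range(3, 1)), c(3, 12))
  expect_equal(unname(sizing_range(24, 1)), c(6, 15))
  expect_equal(n_params(14, 12), 12 * 15 + 13)
})

test_that("forward pass matches hand evaluation and honours the bias", {
  X <- matrix(seq(0, 1, length.out = 10), ncol = 1)
  y <- seq(100, 120, length.out = 10)
  net <- new_network(X, y, 1)
  # all weights zero, output bias beta: constant de-scaled prediction
  net0 <- set_params(net, c(0, 0, 0, 0.25))
  expected <- (0.25 + 1) / 2 * 20 + 100
  expect_equal(unique(predict(net0, X)), expected)
  # hand-set single hidden unit
  th <- c(0.7, 0.1, 0.5, -0.2)
  net1 <- set_params(net, th)
  xs <- 2 * (0.3 - 0) / 1 - 1
  hand <- (0.5 * tanh(0.7 * xs + 0.1) - 0.2 + 1) / 2 * 20 + 100
  expect_equal(predict(net1, matrix(0.3)), hand)
  expect_identical(predict(net1, X), predict(net1, X))
  expect_error(predict(net1, matrix(1, 1, 3)), "dimension")
})

test_that("parameter round trip leaves predictions bit-identical", {
  set.seed(3)
  X <- matrix(rnorm(60), ncol = 3); y <- rnorm(20)
  net <- new_network(X, y, 4, theta = runif(n_params(3, 4), -0.5, 0.5))
  net2 <- set_params(net, get_params(net))
  expect_identical(predict(net, X), predict(net2, X))
  expect_error(set_params(net, c(1, 2)), "mismatch")
  expect_error(set_params(net, rep(NA_real_, length(get_params(net)))), "finite")
})

test_that("min-max scaling and its inverse cancel on training-range data", {
  set.seed(4)
  X <- matrix(runif(40, 2, 9), ncol = 2); y <- runif(20, 80, 130)
  sc <- pulsebp:::fit_scaling(X, y)
  Xs <- pulsebp:::scale_x(X, sc)
  expect_true(all(Xs >= -1 & Xs <= 1))
  expect_equal(pulsebp:::descale_y(pulsebp:::scale_y(y, sc), sc), y,
               tolerance = 1e-12)
})

test_that("Levenberg-Marquardt learns an exactly representable toy map", {
  X <- matrix(seq(0, 1, length.out = 30), ncol = 1)
  y <- 2 * X[, 1]
  net <- train_lm(X, y, 1, train_config(max_epochs = 200, goal_mse = 1e-12,
                                        seed = 2))
  expect_lt(rmse_fitness(net, X, y), 1e-3)
  # constant target: absorbed by the output bias
  yc <- rep(7, 30)
  netc <- train_lm(X, yc, 1, train_config(max_epochs = 50, goal_mse = 1e-16,
                                          seed = 1))
  expect_lt(rmse_fitness(netc, X, yc), 1e-6)
  # determinism
  n1 <- train_lm(X, y, 2, train_config(max_epochs = 30, seed = 9))
  n2 <- train_lm(X, y, 2, train_config(max_epochs = 30, seed = 9))
  expect_identical(get_params(n1), get_params(n2))
  expect_error(train_lm(cbind(c(NA, X[-1, 1])), y, 1), "NA")
})

test_that("accepted LM steps never increase the training error", {
  set.seed(6)
  X <- matrix(runif(80, -1, 1), ncol = 2)
  y <- 100 + 5 * X[, 1] - 3 * X[, 2]^2 + rnorm(40, 0, 0.1)
  net <- train_lm(X, y, 3, train_config(max_epochs = 60, seed = 3))
  trace <- attr(net, "train_mse")
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("LM reaches the solution quality of a numerical-gradient oracle", {
  set.seed(11)
  X <- matrix(runif(30, -1, 1), ncol = 1)
  y <- sin(2 * X[, 1]) * 10 + 100
  lm_net <- train_lm(X, y, 3, train_config(max_epochs = 150, seed = 5))
  # independent oracle: finite-difference gradient descent on the same loss
  proto <- new_network(X, y, 3)
  loss <- function(th) rmse_fitness(set_params(proto, th), X, y)^2
  th <- pulsebp:::with_seed(pulsebp:::derive_seed(5, 31L),
                            runif(length(get_params(proto)), -0.5, 0.5))
  h <- 1e-6; lr <- 0.02
  for (it in seq_len(1500)) {
    g <- vapply(seq_along(th), function(j) {
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (loss(tp) - loss(tm)) / (2 * h)
    }, numeric(1))
    th <- th - lr * g
  }
  r_lm <- rmse_fitness(lm_net, X, y)
  r_gd <- sqrt(loss(th))
  expect_lt(r_lm, r_gd * 1.10)
})

test_that("rmse agrees with hand arithmetic", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(2, 1)), 1)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("network serialization round-trips through JSON", {
  set.seed(2)
  X <- matrix(runif(30), ncol = 3); y <- runif(10, 90, 140)
  net <- train_lm(X, y, 2, train_config(max_epochs = 20, seed = 4))
  p <- withr::local_tempfile(fileext = ".json")
  write_network(net, p)
  net2 <- read_network(p)
  expect_equal(predict(net2, X), predict(net, X), tolerance = 1e-12)
})
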