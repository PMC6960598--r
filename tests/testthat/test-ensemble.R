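# small, fast GA/training settings shared by the ensemble tests
fast_ga <- ga_config(seed = 1, max_generations = 10, n_populations = 2,
                     pop_size = 8)
fast_train <- train_config(max_epochs = 40, seed = 1)

toy_data <- local({
  set.seed(21)
  n <- 100
  X <- cbind(f1 = runif(n, 0, 1), f2 = runif(n, 0, 1), f3 = runif(n, 0, 1))
  y <- 110 + 12 * X[, 1] - 8 * X[, 2] + rnorm(n, 0, 0.5)
  list(X = X, y = y)
})

test_that("fivefold training produces five networks on balanced folds", {
  bm <- train_base_models(toy_data$X, toy_data$y, 2, fast_ga, fast_train,
                          seed = 2)
  expect_length(bm$nets, 5)
  expect_true(all(table(bm$fold) == 20))
  expect_true(all(is.finite(bm$fold_rmse)))
  bm2 <- train_base_models(toy_data$X, toy_data$y, 2, fast_ga, fast_train,
                           seed = 2)
  expect_identical(bm$fold, bm2$fold)
  expect_identical(get_params(bm$nets[[3]]), get_params(bm2$nets[[3]]))
  expect_error(train_base_models(toy_data$X[1:20, ], toy_data$y[1:20], 2,
                                 fast_ga, fast_train), "50 samples")
})

test_that("a constant target is learned by every fold network", {
  X <- toy_data$X
  y <- rep(95, nrow(X))
  bm <- train_base_models(X, y, 2, fast_ga, fast_train, seed = 3)
  for (net in bm$nets) {
    expect_equal(unname(predict(net, X[1:5, ])), rep(95, 5), tolerance = 1e-3)
  }
})

test_that("calibration fits coefficients inside the coding range and beats equal weights", {
  bm_s <- train_base_models(toy_data$X, toy_data$y, 2, fast_ga, fast_train,
                            seed = 4)
  y_d <- toy_data$y - 40
  bm_d <- train_base_models(toy_data$X, y_d, 2, fast_ga, fast_train, seed = 5)
  ens <- new_ensemble(bm_s$nets, bm_d$nets)
  cX <- toy_data$X[1:6, ]
  cys <- toy_data$y[1:6]; cyd <- y_d[1:6]
  cal_cfg <- ga_config(n_populations = 4, pop_size = 10,
                       bits_per_variable = 25, max_generations = 25, seed = 6)
  ens <- calibrate_individual(ens, "T1", cX, cys, cyd, cal_cfg)
  co <- ens$coefficients[["T1"]]
  expect_true(all(co$a >= -0.5 & co$a <= 0.8))
  expect_true(all(co$b >= -0.5 & co$b <= 0.8))
  # calibrated RMSE no worse than the equal-weight (0.2 each) ensemble
  Ps <- sapply(bm_s$nets, function(nn) predict(nn, cX))
  # the equal-weight point sits in the initial gene pool up to coding
  # quantization, so calibration can only improve on it
  eq_rmse <- rmse(cys, drop(Ps %*% rep(0.2, 5)))
  expect_lte(co$rmse_sbp, eq_rmse + 1e-3)
  expect_error(calibrate_individual(ens, "T2", cX[1, , drop = FALSE],
                                    cys[1], cyd[1]), "2 calibration")
})

test_that("calibration approaches the best single base model", {
  bm <- train_base_models(toy_data$X, toy_data$y, 2, fast_ga, fast_train,
                          seed = 7)
  ens <- new_ensemble(bm$nets, bm$nets)
  hits <- 0
  for (sd in 1:5) {
    idx <- 6 * (sd - 1) + 1:6
    cX <- toy_data$X[idx, ]; cy <- toy_data$y[idx]
    cal_cfg <- ga_config(n_populations = 4, pop_size = 10,
                         bits_per_variable = 25, max_generations = 30,
                         seed = sd)
    e2 <- calibrate_individual(ens, "Z", cX, cy, cy, cal_cfg)
    best_single <- min(sapply(bm$nets, function(nn) rmse(cy, predict(nn, cX))))
    if (e2$coefficients$Z$rmse_sbp <= best_single + 0.5) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("prediction is the plain coefficient-weighted sum of base networks", {
  bm <- train_base_models(toy_data$X, toy_data$y, 2, fast_ga, fast_train,
                          seed = 8)
  ens <- new_ensemble(bm$nets, bm$nets)
  Xp <- toy_data$X[1:4, ]
  # unit weight on Nets1 reproduces Nets1 exactly
  ens$coefficients[["A"]] <- list(a = c(1, 0, 0, 0, 0), b = c(1, 0, 0, 0, 0),
                                  rmse_sbp = NA, rmse_dbp = NA)
  p <- predict(ens, "A", Xp)
  expect_equal(p$sbp, unname(predict(bm$nets[[1]], Xp)), tolerance = 1e-12)
  # all-zero coefficients produce an implausible 0 mmHg and a warning
  ens$coefficients[["B"]] <- list(a = rep(0, 5), b = rep(0, 5),
                                  rmse_sbp = NA, rmse_dbp = NA)
  expect_warning(p0 <- predict(ens, "B", Xp), "implausible")
  expect_equal(p0$sbp, rep(0, 4))
  expect_error(predict(ens, "nobody", Xp), "nobody")
})

test_that("ensembles and coefficient tables serialize to CSV", {
  bm <- train_base_models(toy_data$X, toy_data$y, 2, fast_ga, fast_train,
                          seed = 9)
  ens <- new_ensemble(bm$nets, bm$nets)
  ens$coefficients[["I1"]] <- list(a = runif(5, -0.5, 0.8),
                                   b = runif(5, -0.5, 0.8),
                                   rmse_sbp = 1.2, rmse_dbp = 0.9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(ens, p)
  tab <- utils::read.csv(p)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("a1", "b5", "rmse_sbp") %in% names(tab)))
})
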