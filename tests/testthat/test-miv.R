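test_that("impact values respect network structure and symmetry", {
  set.seed(7)
  n <- 100
  X <- cbind(a = runif(n, 1, 3), b = runif(n, 2, 5), dup1 = 0, dup2 = 0)
  X[, "dup1"] <- runif(n, 1, 2); X[, "dup2"] <- X[, "dup1"]
  y <- runif(n, 80, 120)
  net <- new_network(X, y, 2)
  # weights: feature b gets zero input weight everywhere -> MIV exactly 0;
  # dup1/dup2 get identical weights -> identical MIVs
  W1 <- matrix(c(0.3, 0.1,  0, 0,  0.2, 0.4,  0.2, 0.4), nrow = 2)
  th <- c(as.vector(W1), c(0.1, -0.2), c(0.5, 0.8), 0.05)
  net <- set_params(net, th)
  miv <- miv_scores(net, X)
  expect_identical(unname(miv["b"]), 0)
  expect_equal(miv[["dup1"]], miv[["dup2"]], tolerance = 1e-12)
  expect_error(miv_scores(net, X[, 1:2]), "mismatch")
})

test_that("a near-linear network matches the analytic impact values within 1%", {
  set.seed(8)
  n <- 200
  X <- cbind(a = runif(n, 1, 3), b = runif(n, 2, 5), c = runif(n, 0.5, 1.5))
  y <- runif(n, 80, 120)
  net <- new_network(X, y, 2)
  eps <- 1e-3
  W1 <- matrix(runif(6, 0.5, 1.5) * eps, nrow = 2)
  w2 <- c(5, 5)
  net <- set_params(net, c(as.vector(W1), c(0, 0), w2, 0.1))
  miv <- miv_scores(net, X)
  span_x <- apply(X, 2, function(v) diff(range(v)))
  span_y <- diff(range(y))
  slope <- vapply(1:3, function(k)
    sum(w2 * W1[, k]) * (2 / span_x[k]) * (span_y / 2), numeric(1))
  expected <- 0.2 * slope * colMeans(X)
  expect_equal(unname(miv), unname(expected), tolerance = 0.01)
})

test_that("contribution tables normalize, rank and accumulate correctly", {
  tab <- contributions(ref_miv_sbp)
  expect_equal(sum(tab$contribution), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$cumulative) >= 0))
  expect_equal(tab$cumulative[nrow(tab)], 1, tolerance = 1e-9)
  expect_setequal(tab$rank, seq_len(18))
  expect_equal(round(tab$contribution[1], 4), 0.1600)
  expect_equal(round(tab$cumulative[14], 4), 0.8945)
  tab_d <- contributions(ref_miv_dbp)
  expect_equal(round(tab_d$contribution[1], 4), 0.1453)
  expect_equal(round(tab_d$cumulative[14], 4), 0.9104)
  # degenerate cases
  expect_equal(contributions(c(x = 3))$cumulative, 1)
  expect_error(contributions(c(a = 0, b = 0)), "zero")
})

test_that("screening picks the smallest qualifying prefix and is threshold-monotone", {
  tab <- contributions(ref_miv_sbp)
  expect_identical(screen(tab, 0.89), ref_sel_sbp)
  tab_d <- contributions(ref_miv_dbp)
  expect_identical(screen(tab_d, 0.89), ref_sel_dbp)
  expect_length(screen(tab, 1 - 1e-9), 18)
  lens <- vapply(seq(0.05, 0.995, by = 0.05),
                 function(th) length(screen(tab, th)), numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("two-round screening recovers planted causal features", {
  nms <- pulsebp:::feature_names()
  causal <- c("PTT_b", "HR", "BMI")
  hit <- 0
  for (sd in 1:3) {
    set.seed(sd)
    X <- matrix(runif(150 * 24, 1, 2), ncol = 24, dimnames = list(NULL, nms))
    y <- 110 + 25 * X[, "PTT_b"] - 18 * X[, "HR"] + 15 * X[, "BMI"] +
      rnorm(150, 0, 0.3)
    res <- two_round_screen(X, y, 5, train_config(max_epochs = 60, seed = sd),
                            thresholds = c(0.91, 0.89), seed = sd)
    if (all(causal %in% res$selected)) hit <- hit + 1
    expect_lte(length(res$selected), 24)
  }
  expect_equal(hit, 3)
  # permissive thresholds keep everything
  set.seed(1)
  X <- matrix(runif(120 * 4, 1, 2), ncol = 4,
              dimnames = list(NULL, letters[1:4]))
  y <- rowSums(X) * 10 + 50
  res_all <- two_round_screen(X, y, 3, train_config(max_epochs = 40, seed = 1),
                              thresholds = c(1 - 1e-9, 1 - 1e-9), seed = 1)
  expect_length(res_all$selected, 4)
  # determinism
  r1 <- two_round_screen(X, y, 3, train_config(max_epochs = 30, seed = 2),
                         seed = 5)
  r2 <- two_round_screen(X, y, 3, train_config(max_epochs = 30, seed = 2),
                         seed = 5)
  expect_identical(r1, r2)
})
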