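test_that("max_abs_error matches arithmetic and a loop oracle", {
  expect_equal(max_abs_error(c(10, 20), c(10, 20)), 0)
  expect_equal(max_abs_error(c(10, 20), c(12, 26)), 6)
  set.seed(1)
  a <- stats::rnorm(100); b <- stats::rnorm(100)
  worst <- 0
  for (i in 1:100) worst <- max(worst, abs(a[i] - b[i]))
  expect_equal(max_abs_error(a, b), worst)
  expect_error(max_abs_error(1:3, 1:2), "shape error")
})

test_that("the network fits constant and linear targets", {
  set.seed(2)
  X <- matrix(stats::rnorm(240), ncol = 2)
  colnames(X) <- c("age", "iop")
  # constant target
  net <- fit_time_network(X[1:100, ], rep(15, 100),
                          network_spec(epochs = 100), seed = 3)
  expect_lt(max(abs(predict(net, X[1:100, ]) - 15)), 0.1)
  # noiseless linear target: test MSE under 1% of target variance
  t <- 20 + 3 * X[, 1] - 2 * X[, 2]
  net <- fit_time_network(X[1:90, ], t[1:90], network_spec(), seed = 4)
  mse <- mean((predict(net, X[91:120, ]) - t[91:120])^2)
  expect_lt(mse, 0.01 * stats::var(t[91:120]))
  # loss trajectory is recorded and improves
  expect_lt(utils::tail(net$loss, 1), net$loss[1])
})

test_that("training is deterministic in the seed", {
  set.seed(5)
  X <- matrix(stats::rnorm(150), ncol = 3)
  t <- 10 + X[, 1] + abs(X[, 2]) + 0.1 * stats::rnorm(50)
  a <- fit_time_network(X, t, network_spec(epochs = 50), seed = 6)
  b <- fit_time_network(X, t, network_spec(epochs = 50), seed = 6)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  c2 <- fit_time_network(X, t, network_spec(epochs = 50), seed = 7)
  expect_false(identical(a$W1, c2$W1))
})

test_that("the gradient-descent trainer also converges on easy problems", {
  set.seed(8)
  X <- matrix(stats::rnorm(200), ncol = 2)
  t <- 12 + 2 * X[, 1] + stats::rnorm(100, 0, 0.1)
  net <- fit_time_network(X, t, network_spec(algorithm = "gd", epochs = 3000,
                                             learning_rate = 0.05), seed = 9)
  expect_lt(utils::tail(net$loss, 1), 0.05)
  expect_lt(mean((predict(net, X) - t)^2), 0.5)
})

test_that("input contracts are enforced", {
  X <- matrix(stats::rnorm(40), ncol = 2)
  expect_error(fit_time_network(X, rep(1, 10)), "shape error")
  expect_error(fit_time_network(X, rep(-1, 20)), "positive")
  X[1] <- NA
  expect_error(fit_time_network(X, rep(1, 20)), "missing")
})

test_that("configuration scans zero excluded inputs and rank by max error", {
  co <- generate_cohort(seed = 17, n = 400)
  fm <- encode_features(co)
  Xin <- fm$X[, setdiff(colnames(fm$X), "surgery_time")]
  trio <- feature_subset(c("iol_power", "axial_length", "kind_of_surgeon"))
  configs <- c(trio, feature_subset("age"),
               feature_subset(c("age", "iop")))
  scan <- scan_configurations(Xin, co$surgery_time, configs,
                              network_spec(), seed = 18, strata = fm$y)
  expect_equal(nrow(scan), 3)
  expect_false(any(scan$failed))
  # RMSE never exceeds the maximum absolute error
  expect_true(all(scan$rmse <= scan$max_abs_error + 1e-9))
  # the ground-truth configuration dominates noise-only ones
  expect_equal(attr(scan, "best")$mask, trio)
  # single-configuration scan
  one <- scan_configurations(Xin, co$surgery_time, list("age"),
                             network_spec(epochs = 20), seed = 19)
  expect_equal(nrow(one), 1)
  expect_error(scan_configurations(fm$X, co$surgery_time, configs, seed = 1),
               "target")
  expect_error(scan_configurations(Xin, co$surgery_time, list(), seed = 1),
               "non-empty")
})

test_that("a training failure is recorded without aborting the scan", {
  co <- generate_cohort(seed = 20, n = 150)
  fm <- encode_features(co)
  Xin <- fm$X[, setdiff(colnames(fm$X), "surgery_time")]
  # a configuration whose features are absent from X fails cleanly
  Xsub <- Xin[, c("age", "iop")]
  scan <- scan_configurations(Xsub, co$surgery_time,
                              c(feature_subset("age"),
                                feature_subset("axial_length")),
                              network_spec(epochs = 20), seed = 21)
  expect_equal(scan$failed, c(FALSE, TRUE))
  expect_equal(attr(scan, "best")$mask, feature_subset("age"))
})

test_that("compare_times reproduces textbook paired statistics", {
  # identical vectors: zero MSE, degenerate t
  cmp <- compare_times(c(10, 11, 12), c(10, 11, 12))
  expect_equal(cmp$mse, 0)
  expect_true(cmp$degenerate)
  expect_true(is.na(cmp$t))
  # alternating differences: t = 0, p = 1
  cmp <- compare_times(c(1, -1, 1, -1) + 10, rep(10, 4))
  expect_equal(cmp$mean_diff, 0)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$mse, 1)
  # random differences match the direct formulas to 1e-10
  set.seed(22)
  actual <- stats::rnorm(50, 20, 5)
  predicted <- actual + stats::rnorm(50, 0.3, 1)
  cmp <- compare_times(predicted, actual)
  d <- predicted - actual
  t_direct <- mean(d) / (stats::sd(d) / sqrt(50))
  p_direct <- 2 * stats::pt(-abs(t_direct), 49)
  expect_equal(cmp$t, t_direct, tolerance = 1e-10)
  expect_equal(cmp$p, p_direct, tolerance = 1e-10)
  expect_equal(cmp$mse, mean(d^2), tolerance = 1e-12)
  expect_type(cmp$normal, "logical")
  expect_error(compare_times(1:2, 1:2), "at least 3")
})
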