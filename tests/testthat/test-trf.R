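# trf_core module

test_that("make_basis builds unit-peak Hamming windows on the lag grid", {
  # lags -1..1 s at 50 Hz: 101 elements, P = 101 windows
  lags <- seq(round(-1 * 50), round(1 * 50))
  expect_length(lags, 101)
  b <- make_basis(101, width = 50, spacing = 20, fs = 50)
  expect_equal(b$count, 101)
  expect_equal(dim(b$matrix), c(101, 101))
  # 50-ms window on a 20-ms grid: 3 nonzero taps, unit peak
  expect_equal(sum(b$matrix[, 51] != 0), 3)
  expect_equal(max(b$matrix[, 51]), 1)
  expect_equal(which.max(b$matrix[, 51]), 51)
  # all-zero weights reconstruct the zero kernel
  expect_true(all(b$matrix %*% rep(0, 101) == 0))
  expect_error(make_basis(10, width = 5, fs = 50), "smaller than one sample")
})

test_that("predict_forward implements the forward convolution exactly", {
  x <- ts_block(c(1, 0, 0, 2, 0), 50)
  ident <- trf_kernel(matrix(1), 0L, 50, "forward")
  expect_equal(predict_forward(ident, x)$values[, 1], x$values[, 1])

  shift1 <- trf_kernel(matrix(c(0, 1), 2, 1), c(0L, 1L), 50, "forward")
  expect_equal(predict_forward(shift1, ts_block(c(1, 0, 0), 50))$values[, 1],
               c(0, 1, 0))

  zero <- trf_kernel(matrix(0, 5, 3), -2:2, 50, "forward")
  expect_true(all(predict_forward(zero, x)$values == 0))

  expect_error(predict_forward(ident, ts_block(1:5, 100)), "mismatch")
})

test_that("reconstruct_backward implements the k+l convention", {
  y <- ts_block(c(1, 0, 0), 50)
  ident <- trf_kernel(matrix(1), 0L, 50, "backward")
  expect_equal(reconstruct_backward(ident, y)$values[, 1], y$values[, 1])

  # impulse at lag -1: x_hat(k) = y(k - 1)
  back <- trf_kernel(matrix(c(1, 0), 2, 1), c(-1L, 0L), 50, "backward")
  expect_equal(reconstruct_backward(back, y)$values[, 1], c(0, 1, 0))

  # two identical channels, 0.5 each at lag 0
  y2 <- ts_block(cbind(c(1, 2, 3), c(1, 2, 3)), 50)
  half <- trf_kernel(matrix(0.5, 1, 2), 0L, 50, "backward")
  expect_equal(reconstruct_backward(half, y2)$values[, 1], c(1, 2, 3))

  expect_error(reconstruct_backward(half, y), "channel count")
})

test_that("forward and lag-reversed backward kernels are adjoint", {
  set.seed(4)
  h <- rnorm(11)
  lags <- -5:5
  x <- rnorm(400)
  fwd <- trf_kernel(matrix(h), lags, 50, "forward")
  y <- predict_forward(fwd, ts_block(x, 50))
  bwd <- trf_kernel(matrix(rev(h)), lags, 50, "backward")
  xb <- reconstruct_backward(bwd, ts_block(x, 50))
  interior <- 50:350
  expect_equal(y$values[interior, 1], xb$values[interior, 1], tolerance = 1e-9)
})

test_that("pearson_r evaluates the product-moment formula", {
  a <- rnorm(50)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  # scale/shift invariance and symmetry
  b <- rnorm(50)
  expect_equal(pearson_r(a, b), pearson_r(b, a))
  expect_equal(pearson_r(a, 3 * b + 7), pearson_r(a, b))
  expect_error(pearson_r(a, b[1:10]), "length")
  err <- tryCatch(pearson_r(rep(1, 10), rnorm(10)), error = function(e) e)
  expect_s3_class(err, "aadtrf_zero_variance")
})

test_that("boosting recovers a forward kernel from clean data", {
  truth <- synthesize_kernel(rbind(c(40, 0.5, 15), c(100, -1, 25), c(180, 0.7, 35)),
                             c(-0.1, 0.35), 50)
  set.seed(5)
  x <- ts_block(rnorm(120 * 50), 50)
  y <- predict_forward(truth, x)
  fit <- boosting_fit(x, y, lag_range = c(-0.1, 0.35),
                      cfg = boost_config(partitions = 2), direction = "forward")
  expect_gt(pearson_r(fit$coef[, 1], truth$coef[, 1]), 0.9)
  # paper-style grid metadata
  expect_equal(fit$fs, 50)
  expect_equal(fit$direction, "forward")

  # basis closure: returned kernel is exactly sum_p w_p phi_p
  expect_equal(fit$coef, fit$basis$matrix %*% t(fit$weights))
  # sparsity: untouched weights are exactly zero
  expect_true(any(fit$weights == 0))
})

test_that("boosting on independent noise yields a null kernel", {
  set.seed(6)
  x <- ts_block(rnorm(3000), 50)
  y <- ts_block(rnorm(3000), 50)
  fit <- boosting_fit(x, y, lag_range = c(-0.2, 0.2),
                      cfg = boost_config(partitions = 2), direction = "forward")
  expect_lt(mean(abs(fit$coef)), 0.05)
  # out-of-sample prediction carries no information
  x2 <- ts_block(rnorm(3000), 50); y2 <- rnorm(3000)
  pred <- predict_forward(fit, x2)$values[, 1]
  if (sd(pred) > 0)
    expect_lt(abs(pearson_r(pred, y2)), 3 / sqrt(3000))
})

test_that("boosting matches OLS deconvolution on a noiseless toy", {
  set.seed(7)
  x <- rnorm(2000)
  truth <- c(0.5, -1, 0.8, 0.3, -0.2)
  lags <- 0:4
  y <- as.numeric(sapply(lags, function(l) aadtrf:::shift_zero(x, l)) %*% truth)
  h_ols <- ols_deconv(x, y, lags)
  y_ols <- as.numeric(sapply(lags, function(l) aadtrf:::shift_zero(x, l)) %*% h_ols)
  fit <- boosting_fit(ts_block(x, 50), ts_block(y, 50), lag_range = c(0, 0.08),
                      cfg = boost_config(partitions = 2), direction = "forward")
  y_boost <- predict_forward(fit, ts_block(x, 50))$values[, 1]
  rho_ols <- pearson_r(y_ols, y)
  rho_boost <- pearson_r(y_boost, y)
  expect_lt(abs(rho_ols - rho_boost), 0.02)
})

test_that("boosting handles degenerate input and mismatched segments", {
  x <- ts_block(rnorm(500), 50)
  expect_warning(
    boosting_fit(x, ts_block(rep(1, 500), 50), lag_range = c(0, 0.1),
                 cfg = boost_config(partitions = 2), direction = "forward"),
    "degenerate")
  expect_error(
    boosting_fit(x, ts_block(rnorm(400), 50), lag_range = c(0, 0.1)),
    "equal durations")
})

test_that("backward boosting reconstructs the driving feature", {
  # EEG channels = lagged noisy copies of the feature
  set.seed(8)
  n <- 6000
  feat <- rnorm(n)
  eeg <- cbind(aadtrf:::shift_zero(feat, 3) + 0.3 * rnorm(n),
               aadtrf:::shift_zero(feat, 6) + 0.3 * rnorm(n))
  fit <- boosting_fit(ts_block(eeg, 50), ts_block(feat, 50),
                      lag_range = c(-0.2, 0.2),
                      cfg = boost_config(partitions = 2), direction = "backward")
  xhat <- reconstruct_backward(fit, ts_block(eeg, 50))
  expect_gt(pearson_r(xhat$values[, 1], feat), 0.85)
  # energy concentrated at the true lags (+3, +6 samples)
  pk <- order(colSums(abs(fit$coef[, ])), decreasing = TRUE)
  best_lags <- fit$lags[apply(abs(fit$coef), 2, which.max)]
  expect_setequal(best_lags, c(3L, 6L))
})
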