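# eeg_preprocessing module

test_that("rereference subtracts the group reference", {
  mont <- default_montage(4, 8)
  set.seed(2)
  v <- matrix(rnorm(12 * 200), 200, 12)
  colnames(v) <- c(mont$scalp, mont$ceegrid)
  eeg <- ts_block(v, 100, c(mont$scalp, mont$ceegrid))

  ca <- rereference(eeg, mont, "common_average")
  expect_lt(max(abs(rowMeans(ca$values[, mont$scalp]))), 1e-12)
  expect_equal(ca$values[, mont$ceegrid], v[, mont$ceegrid])

  # L4 = R4 = 0: other cEEGrid channels unchanged
  v2 <- v; v2[, c("L4", "R4")] <- 0
  lr <- rereference(ts_block(v2, 100, eeg$channels), mont, "linked_L4R4")
  others <- setdiff(mont$ceegrid, c("L4", "R4"))
  expect_equal(lr$values[, others], v2[, others])

  # constant offset removed by common average
  off <- ts_block(matrix(5, 100, 4), 100, mont$scalp)
  expect_true(all(rereference(off, mont, "common_average")$values == 0))

  bad <- ts_block(v[, 1:6], 100, c(mont$scalp, "L1", "R1"))
  expect_error(rereference(bad, mont, "linked_L4R4"), "L4/R4")
})

test_that("fir_bandpass passes the band and rejects drift, zero phase", {
  fs <- 50; tt <- (0:(fs * 120 - 1)) / fs
  x5 <- ts_block(sin(2 * pi * 5 * tt), fs)
  y5 <- fir_bandpass(x5, 1, 20)
  g <- interior_ratio(y5$values[, 1], x5$values[, 1])
  expect_true(g >= 0.98 && g <= 1.02)
  # zero net phase: cross-correlation peak at lag 0
  cc <- ccf(y5$values[1500:4500, 1], x5$values[1500:4500, 1],
            lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  fs <- 100; tt <- (0:(fs * 400 - 1)) / fs
  drift <- ts_block(sin(2 * pi * 0.01 * tt), fs)
  yd <- fir_bandpass(drift, 0.1, 40)
  expect_lt(20 * log10(interior_ratio(yd$values[, 1], drift$values[, 1])), -20)

  z <- fir_bandpass(ts_block(numeric(500), 100), 1, 20)
  expect_true(all(z$values == 0))

  expect_error(fir_bandpass(ts_block(rnorm(100), 50), 1, 30), "Nyquist")
})

test_that("notch_filter removes line noise and spares distant bands", {
  fs <- 500; tt <- (0:(fs * 20 - 1)) / fs
  x50 <- ts_block(sin(2 * pi * 50 * tt), fs)
  y50 <- notch_filter(x50, 50)
  expect_lte(interior_ratio(y50$values[, 1], x50$values[, 1]), 0.032)

  x10 <- ts_block(sin(2 * pi * 10 * tt), fs)
  y10 <- notch_filter(x10, 50)
  expect_lt(abs(interior_ratio(y10$values[, 1], x10$values[, 1]) - 1), 0.01)

  z <- notch_filter(ts_block(numeric(1000), fs), 50)
  expect_true(all(z$values == 0))

  expect_error(notch_filter(ts_block(rnorm(100), 80), 50), "Nyquist")
})

test_that("resample preserves duration, DC and in-band sinusoids", {
  x <- ts_block(rnorm(9000), 500)
  r <- resample(x, 50)
  expect_equal(nrow(r$values), 900)
  expect_equal(r$fs, 50)

  dc <- resample(ts_block(rep(3.3, 5000), 500), 50)
  expect_equal(dc$values[40:460, 1], rep(3.3, 421), tolerance = 1e-12)

  fs <- 500; tt <- (0:(fs * 60 - 1)) / fs
  s5 <- ts_block(sin(2 * pi * 5 * tt), fs)
  r5 <- resample(s5, 50)
  gain <- rms(r5$values[500:2500, 1]) / rms(s5$values[5000:25000, 1])
  expect_lt(abs(gain - 1), 0.01)

  expect_error(resample(x, 1000), "upsampling")

  # non-integer ratio falls back to FFT resampling, duration within a sample
  r2 <- resample(ts_block(rnorm(4410), 441), 100)
  expect_lte(abs(nrow(r2$values) - 1000), 1)
})

test_that("normalize_channels z-scores per channel and flags constants", {
  set.seed(3)
  x <- ts_block(matrix(rnorm(600, 5, 3), 200, 3), 50)
  nz <- normalize_channels(x)
  expect_lt(max(abs(colMeans(nz$values))), 1e-9)
  expect_equal(apply(nz$values, 2, sd), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
  # idempotent
  expect_equal(normalize_channels(nz)$values, nz$values, tolerance = 1e-9)

  bad <- ts_block(cbind(rnorm(100), rep(2, 100)), 50, c("good", "flat"))
  err <- tryCatch(normalize_channels(bad), error = function(e) e)
  expect_s3_class(err, "aadtrf_flagged_channel")
  expect_match(conditionMessage(err), "flat")
})

test_that("the preprocessing chain enforces the canonical stage order", {
  expect_true(aadtrf:::assert_chain_order(aadtrf:::eeg_chain_stages()))
  expect_error(
    aadtrf:::assert_chain_order(rev(aadtrf:::eeg_chain_stages())),
    "out of order")
  expect_error(
    preprocess_eeg(ts_block(rnorm(100), 200), default_montage(1, 0),
                   stages = c("notch", "rereference")),
    "out of order")
})

test_that("preprocess_eeg output is 50 Hz, normalized, and bit-reproducible", {
  cfg <- tiny_cfg(duration = 20, n_scalp = 3, n_ceegrid = 8,
                  counts = c(SustAC = 1, SwitAC = 0, ConvAC = 0))
  tr <- synthesize_trial(cfg, default_ground_truth(cfg), "SustAC", seed = 9)
  out1 <- preprocess_eeg(tr$eeg, default_montage(3, 8))
  out2 <- preprocess_eeg(tr$eeg, default_montage(3, 8))
  expect_identical(out1$values, out2$values)
  expect_equal(out1$fs, 50)
  expect_lt(max(abs(colMeans(out1$values))), 1e-9)
  expect_equal(unname(apply(out1$values, 2, sd)), rep(1, 11), tolerance = 1e-9)
  expect_equal(nrow(out1$values), 1000)
  log <- attr(out1, "log")
  expect_identical(names(log), aadtrf:::eeg_chain_stages())
})
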