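# synthetic_data module

test_that("synthesize_envelope is nonnegative, syllabic, and deterministic", {
  env <- synthesize_envelope(180, 50, seed = 1)
  expect_equal(nrow(env$values), 9000)  # 180 s x 50 Hz
  expect_true(all(env$values >= 0))

  e1 <- synthesize_envelope(10, 50, seed = 7)
  e2 <- synthesize_envelope(10, 50, seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(e1, synthesize_envelope(10, 50, seed = 8)))

  # dominant spectral content below 10 Hz
  v <- synthesize_envelope(60, 50, seed = 3)$values[, 1]
  pg <- stats::spec.pgram(v - mean(v), plot = FALSE, taper = 0)
  f <- pg$freq * 50
  expect_gt(sum(pg$spec[f < 10]) / sum(pg$spec), 0.8)

  expect_error(synthesize_envelope(-1, 50, 1), "positive")
  expect_error(synthesize_envelope(10, 0, 1), "positive")
})

test_that("synthesize_kernel places Gaussian bumps on the lag grid", {
  k0 <- synthesize_kernel(rbind(c(0, 1.0, 10)), c(-0.1, 0.1), 100)
  expect_equal(k0$lags[which.max(k0$coef[, 1])], 0L)

  k3 <- synthesize_kernel(rbind(c(40, 0.5, 20), c(100, -1.0, 25), c(180, 0.8, 35)),
                          c(-0.2, 0.5), 200)
  lag_ms <- k3$lags / k3$fs * 1000
  neg <- k3$coef[, 1] < 0
  # exactly one negative extremum, at 100 ms
  expect_equal(lag_ms[which.min(k3$coef[, 1])], 100)
  runs <- rle(neg)
  expect_equal(sum(runs$values), 1L)

  # zeros beyond four widths from any bump
  k1 <- synthesize_kernel(rbind(c(100, 1, 10)), c(-0.5, 0.5), 100)
  far <- abs(k1$lags / 100 - 0.1) > 4 * 0.010
  expect_true(all(k1$coef[far, 1] == 0))

  expect_equal(synthesize_kernel(list(), c(0, 0.2), 50)$coef[, 1],
               rep(0, 11))
  expect_error(synthesize_kernel(rbind(c(400, 1, 10)), c(0, 0.2), 50),
               "outside lag_range")
})

test_that("synthesize_trial honors condition protocols", {
  cfg <- tiny_cfg(duration = 30, counts = c(SustAC = 1, SwitAC = 1, ConvAC = 1))
  truth <- default_ground_truth(cfg)

  sus <- synthesize_trial(cfg, truth, "SustAC", seed = 2)
  expect_equal(nrow(sus$schedule), 1L)
  expect_equal(sus$schedule$start, 0)
  expect_equal(sus$schedule$end, 30)

  swi <- synthesize_trial(cfg, truth, "SwitAC", seed = 2)
  expect_equal(nrow(swi$schedule), 3L)
  sw <- swi$schedule$start[-1]
  expect_true(sw[1] >= cfg$switch_window_1[1] && sw[1] <= cfg$switch_window_1[2])
  expect_true(sw[2] >= cfg$switch_window_2[1] && sw[2] <= cfg$switch_window_2[2])
  # schedule tiles the trial without overlap
  expect_equal(swi$schedule$start[-1], swi$schedule$end[-3])

  conv <- synthesize_trial(cfg, truth, "ConvAC", seed = 2)
  expect_equal(nrow(conv$schedule), 1L)
  expect_setequal(conv$competing, c("conv", "side"))
  expect_true("control" %in% names(conv$streams))

  expect_error(synthesize_trial(cfg, truth, "XyzAC", seed = 1), "unknown condition")
})

test_that("trial EEG equals kernel-convolved attended stream at high SNR", {
  cfg <- tiny_cfg(duration = 30, n_scalp = 1, snr_db = 60, gain = 1e-6,
                  counts = c(SustAC = 1, SwitAC = 0, ConvAC = 0))
  truth <- default_ground_truth(cfg)
  truth$channel_topography <- 1
  tr <- synthesize_trial(cfg, truth, "SustAC", seed = 2)
  direct <- aadtrf:::apply_kernel_vec(tr$streams$S1$values[, 1],
                                      truth$attended_kernel$coef[, 1],
                                      truth$attended_kernel$lags)
  expect_gt(pearson_r(tr$eeg$values[, 1], direct), 0.99)
})

test_that("realized SNR matches the configured snr_db within 1 dB", {
  for (snr in c(0, 10)) {
    cfg <- tiny_cfg(duration = 60, n_scalp = 4, snr_db = snr)
    truth <- default_ground_truth(cfg)
    tr <- synthesize_trial(cfg, truth, "SustAC", seed = 11)
    s1 <- tr$streams$S1$values[, 1]; s2 <- tr$streams$S2$values[, 1]
    clean1 <- aadtrf:::apply_kernel_vec(s1 - mean(s1),
                                        truth$attended_kernel$coef[, 1],
                                        truth$attended_kernel$lags) +
      cfg$attention_gain * aadtrf:::apply_kernel_vec(
        s2 - mean(s2), truth$ignored_kernel$coef[, 1], truth$ignored_kernel$lags)
    clean <- outer(clean1, truth$channel_topography)
    noise <- tr$eeg$values - clean
    realized <- 10 * log10(mean(colMeans(clean^2)) / mean(colMeans(noise^2)))
    expect_lt(abs(realized - snr), 1)
  }
})

test_that("control stream is independent of the EEG", {
  cfg <- tiny_cfg(duration = 60, n_scalp = 3, snr_db = 10)
  sess <- preprocess_session(synthesize_session(cfg, seed = 4))
  tr <- sess$trials[[1]]
  ctl <- composite_feature(tr, "control")$values[, 1]
  n <- length(ctl)
  for (ch in seq_len(3))
    expect_lt(abs(pearson_r(tr$eeg$values[, ch], ctl)), 3 / sqrt(n))
})

test_that("attention asymmetry holds in expectation over seeds", {
  cfg <- tiny_cfg(duration = 20, n_scalp = 2, snr_db = 5, gain = 0.4,
                  counts = c(SustAC = 1, SwitAC = 0, ConvAC = 0))
  truth <- default_ground_truth(cfg)
  xc_peak <- function(eeg, feat) {
    cc <- ccf(eeg, feat, lag.max = 100, plot = FALSE)
    max(abs(cc$acf))
  }
  d <- vapply(1:20, function(s) {
    tr <- synthesize_trial(cfg, truth, "SustAC", seed = s)
    xc_peak(tr$eeg$values[, 1], tr$streams$S1$values[, 1]) -
      xc_peak(tr$eeg$values[, 1], tr$streams$S2$values[, 1])
  }, 0)
  expect_gt(mean(d), 0)
})

test_that("synthesize_session builds the configured protocol deterministically", {
  # default trial counts (8 + 8 + 9), scaled-down duration/channels
  cfg <- tiny_cfg(duration = 4, n_scalp = 1, fs_raw = 150,
                  counts = c(SustAC = 8, SwitAC = 8, ConvAC = 9),
                  sw1 = c(1, 1.5), sw2 = c(2, 2.5))
  sess <- synthesize_session(cfg, seed = 5)
  expect_length(sess$trials, 25)
  expect_equal(as.integer(table(aadtrf:::session_conditions(sess))[c("SustAC", "SwitAC", "ConvAC")]),
               c(8L, 8L, 9L))

  expect_identical(sess, synthesize_session(cfg, seed = 5))
  expect_false(identical(sess, synthesize_session(cfg, seed = 6)))

  cfg2 <- tiny_cfg(duration = 4, n_scalp = 1, fs_raw = 150,
                   counts = c(SustAC = 2, SwitAC = 0, ConvAC = 0),
                   sw1 = c(1, 1.5), sw2 = c(2, 2.5))
  s2 <- synthesize_session(cfg2, seed = 1)
  expect_length(s2$trials, 2)
  expect_true(all(aadtrf:::session_conditions(s2) == "SustAC"))

  # montage split
  cfg3 <- tiny_cfg(duration = 4, n_scalp = 4, n_ceegrid = 8, fs_raw = 150,
                   counts = c(SustAC = 1, SwitAC = 0, ConvAC = 0),
                   sw1 = c(1, 1.5), sw2 = c(2, 2.5))
  s3 <- synthesize_session(cfg3, seed = 1)
  expect_length(s3$montage$scalp, 4)
  expect_length(s3$montage$ceegrid, 8)
  expect_true(all(c("L4", "R4") %in% s3$montage$ceegrid))
})

test_that("sim_config validates its invariants", {
  expect_error(tiny_cfg(duration = -2), "trial_duration")
  expect_error(tiny_cfg(gain = 0), "attention_gain")
  expect_error(tiny_cfg(gain = 1.5), "attention_gain")
  expect_error(tiny_cfg(sw1 = c(18, 22), sw2 = c(8, 12)), "precede")
})

test_that("synthesize_probe_audio produces calibrated fixtures", {
  tone <- synthesize_probe_audio("pure_tone", f0 = 1000, duration = 1, fs = 44100)
  pg <- stats::spec.pgram(tone$values[, 1], plot = FALSE, taper = 0)
  expect_equal(pg$freq[which.max(pg$spec)] * 44100, 1000, tolerance = 1)

  expect_true(all(synthesize_probe_audio("silence", duration = 1, fs = 44100)$values == 0))
  expect_error(synthesize_probe_audio("pure_tone", f0 = 30000, duration = 1, fs = 44100),
               "aliasing")

  # AM noise: rectified-and-smoothed envelope peaks at the modulation rate
  am <- synthesize_probe_audio("am_noise", fm = 4, duration = 10, fs = 8000)
  env <- resample(ts_block(abs(am$values[, 1]), 8000), 100)
  v <- env$values[, 1] - mean(env$values[, 1])
  pg <- stats::spec.pgram(v, plot = FALSE, taper = 0)
  expect_equal(pg$freq[which.max(pg$spec)] * 100, 4, tolerance = 0.2)
})
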