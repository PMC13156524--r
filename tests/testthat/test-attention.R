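# attention_eval module

test_that("make_folds is leave-one-trial-out with no overlap", {
  cfg <- tiny_cfg(duration = 4, n_scalp = 1, fs_raw = 150,
                  counts = c(SustAC = 8, SwitAC = 0, ConvAC = 2),
                  sw1 = c(1, 1.5), sw2 = c(2, 2.5))
  sess <- synthesize_session(cfg, seed = 3)
  folds <- make_folds(sess, "SustAC")
  expect_length(folds, 8)
  tests <- vapply(folds, function(f) f$test, 0L)
  expect_setequal(tests, which(aadtrf:::session_conditions(sess) == "SustAC"))
  for (f in folds) {
    expect_length(f$train, 7)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_length(make_folds(sess, "ConvAC"), 2)
  expect_error(make_folds(sess, "SwitAC"), "at least 2")
})

test_that("score_reconstruction segments trials and excludes switch straddles", {
  # oracle injection: EEG channel 1 equals the attended feature, kernel is an
  # impulse, so x_hat == attended exactly
  set.seed(9)
  n <- 180 * 50
  att <- rnorm(n); ign <- rnorm(n); ctl <- rnorm(n)
  tr <- manual_trial(att, ign, ctl, ts_block(att, 50, "E1"))
  kern <- trf_kernel(matrix(1), 0L, 50, "backward", channels = "E1")
  sc <- score_reconstruction(kern, tr, 35)
  expect_equal(nrow(sc), 5)  # floor(180 / 35)
  expect_equal(sc$rho_att, rep(1, 5))
  expect_true(all(abs(sc$rho_ign) < 1))

  # SwitAC with switches at 45 and 135 s, 35-s windows: segments 2 and 4 straddle
  sched <- data.frame(start = c(0, 45, 135), end = c(45, 135, 180),
                      stream = c("S1", "S2", "S1"))
  tr2 <- manual_trial(att, ign, ctl, ts_block(att, 50, "E1"),
                      condition = "SwitAC", schedule = sched)
  sc2 <- score_reconstruction(kern, tr2, 35)
  expect_equal(sc2$segment, c(1L, 3L, 5L))
  expect_equal(attr(sc2, "n_excluded"), 2L)

  expect_error(score_reconstruction(kern, tr, 200), "usable duration")
})

test_that("classify_attention compares correlations with a conservative tie rule", {
  sc <- data.frame(rho_att = c(0.5, 0.2, 0.3), rho_ign = c(0.1, 0.1, 0.1))
  ev <- classify_attention(sc)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$n, 3)

  tie <- classify_attention(data.frame(rho_att = 0.4, rho_ign = 0.4))
  expect_equal(tie$accuracy, 0)

  # null scores: accuracy within the 95% binomial band around 0.5
  set.seed(10)
  null <- data.frame(rho_att = rnorm(100), rho_ign = rnorm(100))
  acc <- classify_attention(null)$accuracy
  band <- qbinom(c(0.025, 0.975), 100, 0.5) / 100
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("decision_window_curve drops invalid windows and aggregates folds", {
  sess <- cached_session("att_small", function() {
    preprocess_session(synthesize_session(
      tiny_cfg(duration = 40, n_scalp = 2, snr_db = 10,
               counts = c(SustAC = 3, SwitAC = 3, ConvAC = 0),
               sw1 = c(10, 14), sw2 = c(24, 28), seed = 21), seed = 21))
  })
  expect_message(
    cv <- decision_window_curve(sess, "SwitAC", lengths = c(5, 178),
                                lag_range = c(0, 0.3), cfg = fast_boost()),
    "178")
  expect_false(178 %in% cv$curve$window_s)

  # full-trial window on SustAC: exactly one decision per trial
  cv2 <- decision_window_curve(sess, "SustAC", lengths = 40,
                               lag_range = c(0, 0.3), cfg = fast_boost())
  expect_equal(cv2$curve$n, 3)

  expect_message(
    decision_window_curve(sess, "SustAC", lengths = c(10, 90),
                          lag_range = c(0, 0.3), cfg = fast_boost(),
                          kernels = cv2$kernels),
    "longer than the trial")
})

test_that("relabeling the test trial flips decisions but not kernels", {
  sess <- cached_session("att_small", function() {
    preprocess_session(synthesize_session(
      tiny_cfg(duration = 40, n_scalp = 2, snr_db = 10,
               counts = c(SustAC = 3, SwitAC = 3, ConvAC = 0),
               sw1 = c(10, 14), sw2 = c(24, 28), seed = 21), seed = 21))
  })
  folds <- make_folds(sess, "SustAC")
  kern <- fit_decoder(sess, folds[[1]]$train, lag_range = c(0, 0.3),
                      cfg = fast_boost())
  trial <- sess$trials[[folds[[1]]$test]]
  sc <- score_reconstruction(kern, trial, 10)

  flipped <- trial
  flipped$schedule$stream <- "S2"  # relabel: S2 now "attended"
  sc_f <- score_reconstruction(kern, flipped, 10)
  expect_equal(sc$rho_att, sc_f$rho_ign)
  expect_equal(sc$rho_ign, sc_f$rho_att)
  expect_equal(classify_attention(sc)$scores$correct,
               !classify_attention(sc_f)$scores$correct)

  # kernels are fitted on training trials only: refit is identical
  kern2 <- fit_decoder(sess, folds[[1]]$train, lag_range = c(0, 0.3),
                       cfg = fast_boost())
  expect_identical(kern$coef, kern2$coef)
})

test_that("accuracy responds monotonically to SNR", {
  snrs <- c(-20, -10, 0, 10)
  mean_acc <- vapply(snrs, function(snr) {
    accs <- vapply(1:6, function(s) {
      sess <- preprocess_session(synthesize_session(
        tiny_cfg(duration = 30, n_scalp = 2, snr_db = snr,
                 counts = c(SustAC = 3, SwitAC = 0, ConvAC = 0), seed = s),
        seed = s))
      cv <- decision_window_curve(sess, "SustAC", lengths = 10,
                                  lag_range = c(0, 0.3),
                                  cfg = boost_config(partitions = 2,
                                                     max_steps = 150))
      cv$curve$accuracy
    }, 0)
    mean(accs)
  }, 0)
  expect_gte(cor(mean_acc, seq_along(snrs), method = "spearman"), 0)
  expect_gt(mean_acc[4], mean_acc[1])
})

test_that("cross_condition_eval redirects within-condition requests to CV", {
  sess <- cached_session("att_small", function() {
    preprocess_session(synthesize_session(
      tiny_cfg(duration = 40, n_scalp = 2, snr_db = 10,
               counts = c(SustAC = 3, SwitAC = 3, ConvAC = 0),
               sw1 = c(10, 14), sw2 = c(24, 28), seed = 21), seed = 21))
  })
  within <- cross_condition_eval(sess, "SustAC", "SustAC", window = 10,
                                 lag_range = c(0, 0.3), cfg = fast_boost())
  cv <- decision_window_curve(sess, "SustAC", lengths = 10,
                              lag_range = c(0, 0.3), cfg = fast_boost())
  expect_equal(within$accuracy, cv$curve$accuracy)
  expect_true(within$accuracy >= 0 && within$accuracy <= 1)
})

test_that("optimal_lag_scan covers 78 windows with 2-3 taps each", {
  starts <- seq(-600, 600 - 45, by = 15)
  expect_length(starts, 78)
  fs <- 50
  all_lags <- seq(-0.6 * fs, 0.6 * fs)
  tap_counts <- vapply(starts + 22.5, function(cms)
    sum(abs(all_lags / fs * 1000 - cms) < 22.5), 0)
  expect_true(all(tap_counts %in% 2:3))
})
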