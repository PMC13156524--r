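# Attention decoding: leave-one-trial-out cross-validation, reconstruction
# correlations for attended/ignored/control streams, decision-window
# classification, cross-condition generalization, and the sliding optimal-lag
# analysis.

# correlation with a no-information (zero-variance) signal scores 0
safe_rho <- function(a, b)
  tryCatch(pearson_r(a, b), aadtrf_zero_variance = function(e) 0)

#' Schedule-spliced stream feature
#'
#' Builds the composite attended (or ignored / control) feature of a trial by
#' splicing the competing streams according to the attention schedule.
#'
#' @param trial preprocessed `aad_trial`.
#' @param role `"attended"`, `"ignored"` or `"control"`.
#' @return single-channel [ts_block()] aligned with the trial's EEG.
#' @export
composite_feature <- function(trial, role = c("attended", "ignored", "control")) {
  role <- match.arg(role)
  n <- n_samples(trial$eeg)
  fs <- trial$eeg$fs
  if (role == "control")
    return(ts_block(trial$streams[[trial$control]]$values[seq_len(n), 1], fs, "control"))
  out <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(trial$schedule))) {
    sel <- tt >= trial$schedule$start[i] & tt < trial$schedule$end[i]
    a_id <- trial$schedule$stream[i]
    id <- if (role == "attended") a_id else setdiff(trial$competing, a_id)
    out[sel] <- trial$streams[[id]]$values[which(sel), 1]
  }
  ts_block(out, fs, role)
}

#' Leave-one-trial-out fold plan
#'
#' @param session an `aad_session`.
#' @param condition condition label to cross-validate within.
#' @return list of folds, each `list(train = trial indices, test = index)`;
#'   every trial of the condition serves as test exactly once.
#' @export
make_folds <- function(session, condition) {
  idx <- which(session_conditions(session) == condition)
  if (length(idx) < 2)
    stop("need at least 2 trials in condition ", condition, call. = FALSE)
  lapply(seq_along(idx), function(i) {
    fold <- list(train = idx[-i], test = idx[i])
    stopifnot(length(intersect(fold$train, fold$test)) == 0)
    fold
  })
}

eeg_subset <- function(eeg, channels = NULL) {
  if (is.null(channels)) return(eeg)
  missing <- setdiff(channels, eeg$channels)
  if (length(missing)) stop("channels not present: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  ts_block(eeg$values[, channels, drop = FALSE], eeg$fs, channels)
}

#' Fit a backward decoder on a set of trials
#'
#' Convenience wrapper around [boosting_fit()]: EEG (optionally restricted to
#' a channel subset) is regressed onto the schedule-spliced attended feature
#' of every included trial.
#'
#' @param session preprocessed `aad_session`.
#' @param trial_idx indices of training trials.
#' @param lag_range TRF lag range in seconds.
#' @param cfg a [boost_config()].
#' @param channels optional channel subset.
#' @param target `"attended"` (default), `"ignored"` or `"control"`.
#' @param lags optional explicit lag vector (samples).
#' @return backward [trf_kernel()].
#' @export
fit_decoder <- function(session, trial_idx, lag_range = c(-1, 1),
                        cfg = boost_config(), channels = NULL,
                        target = "attended", lags = NULL) {
  if (!isTRUE(session$preprocessed))
    stop("session must be preprocessed first", call. = FALSE)
  inputs <- lapply(session$trials[trial_idx],
                   function(tr) eeg_subset(tr$eeg, channels))
  targets <- lapply(session$trials[trial_idx], composite_feature, role = target)
  boosting_fit(inputs, targets, lag_range = lag_range, cfg = cfg,
               direction = "backward", lags = lags)
}

#' Score reconstructions of a held-out trial
#'
#' Reconstructs the stimulus feature from the trial's EEG once, splits the
#' trial into consecutive non-overlapping decision windows, and correlates
#' each window of the reconstruction with the attended, ignored and control
#' features. Windows that straddle an attention switch (SwitAC) are excluded.
#'
#' @param kernel backward [trf_kernel()] fitted without this trial.
#' @param trial preprocessed `aad_trial`.
#' @param window decision-window length in seconds.
#' @return data.frame with one row per retained window: `segment`, `t_start`,
#'   `t_end`, `rho_att`, `rho_ign`, `rho_ctl`; excluded window count in
#'   `attr(, "n_excluded")`.
#' @export
score_reconstruction <- function(kernel, trial, window) {
  dur <- block_duration(trial$eeg)
  if (window > dur) stop("window exceeds usable duration", call. = FALSE)
  fs <- trial$eeg$fs
  xhat <- reconstruct_backward(kernel, eeg_subset(trial$eeg, kernel$channels))$values[, 1]
  att <- composite_feature(trial, "attended")$values[, 1]
  ign <- composite_feature(trial, "ignored")$values[, 1]
  ctl <- composite_feature(trial, "control")$values[, 1]
  nseg <- floor(dur / window)
  switches <- trial$schedule$start[-1]
  rows <- list(); excl <- 0L
  for (s in seq_len(nseg)) {
    t0 <- (s - 1) * window; t1 <- s * window
    if (any(switches > t0 & switches < t1)) { excl <- excl + 1L; next }
    i0 <- floor(t0 * fs) + 1L; i1 <- floor(t1 * fs)
    idx <- i0:i1
    # an all-zero decoder (e.g. under pure noise) carries no information:
    # its reconstruction scores rho = 0 and falls to the conservative tie rule
    rows[[length(rows) + 1L]] <- data.frame(
      segment = s, t_start = t0, t_end = t1,
      rho_att = safe_rho(xhat[idx], att[idx]),
      rho_ign = safe_rho(xhat[idx], ign[idx]),
      rho_ctl = safe_rho(xhat[idx], ctl[idx]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment = integer(), t_start = numeric(), t_end = numeric(),
               rho_att = numeric(), rho_ign = numeric(), rho_ctl = numeric())
  attr(out, "n_excluded") <- excl
  out
}

#' Classify attention from reconstruction scores
#'
#' A window is decided "attended" iff `rho_att > rho_ign`; exact ties are
#' scored incorrect (conservative). Accuracy is the fraction of correct
#' decisions.
#'
#' @param scores data.frame with `rho_att` and `rho_ign` columns (e.g. from
#'   [score_reconstruction()], possibly row-bound over folds).
#' @return an `aad_eval`: the scores with a `correct` column, plus `accuracy`
#'   and `n`.
#' @export
classify_attention <- function(scores) {
  if (!nrow(scores)) stop("no scores to classify", call. = FALSE)
  scores$correct <- scores$rho_att > scores$rho_ign
  structure(list(scores = scores, accuracy = mean(scores$correct),
                 n = nrow(scores)),
            class = "aad_eval")
}

#' @export
print.aad_eval <- function(x, ...) {
  cat(sprintf("<aad_eval> accuracy %.3f over %d decisions\n", x$accuracy, x$n))
  invisible(x)
}

default_window_grid <- function() c(1.1, 2.2, 4.4, 8.8, 17.5, 35, 178)

#' Decision-window accuracy curve
#'
#' Leave-one-trial-out classification accuracy as a function of
#' decision-window length. Kernels are fitted once per fold and reused across
#' window lengths. The 178-s (full-trial) window is dropped for SwitAC, whose
#' switches make full-trial decisions undefined; windows longer than the
#' trial are dropped with a message.
#'
#' @param session preprocessed `aad_session`.
#' @param condition condition to evaluate.
#' @param lengths decision-window grid in seconds.
#' @param lag_range,cfg,channels decoder settings, see [fit_decoder()].
#' @param kernels optional list of pre-fitted per-fold kernels (one per fold
#'   of [make_folds()]), e.g. to share fits across analyses.
#' @return an `aad_curve`: `curve` data.frame (`window_s`, `n`, `accuracy`),
#'   per-window details, fold kernels.
#' @export
decision_window_curve <- function(session, condition,
                                  lengths = default_window_grid(),
                                  lag_range = c(-1, 1), cfg = boost_config(),
                                  channels = NULL, kernels = NULL) {
  dur <- block_duration(session$trials[[which(session_conditions(session) == condition)[1]]]$eeg)
  if (condition == "SwitAC" && any(lengths >= 178)) {
    message("dropping 178-s window for SwitAC (switches preclude full-trial decisions)")
    lengths <- lengths[lengths < 178]
  }
  if (any(lengths > dur)) {
    message("dropping windows longer than the trial (", dur, " s)")
    lengths <- lengths[lengths <= dur]
  }
  folds <- make_folds(session, condition)
  if (is.null(kernels))
    kernels <- lapply(folds, function(f)
      fit_decoder(session, f$train, lag_range = lag_range, cfg = cfg,
                  channels = channels))
  details <- list()
  for (i in seq_along(folds)) {
    trial <- session$trials[[folds[[i]]$test]]
    for (w in lengths) {
      sc <- score_reconstruction(kernels[[i]], trial, w)
      if (!nrow(sc)) next
      sc$fold <- i; sc$window_s <- w
      details[[length(details) + 1L]] <- sc
    }
  }
  details <- do.call(rbind, details)
  curve <- do.call(rbind, lapply(sort(unique(details$window_s)), function(w) {
    ev <- classify_attention(details[details$window_s == w, ])
    data.frame(window_s = w, n = ev$n, accuracy = ev$accuracy)
  }))
  structure(list(curve = curve, details = details, condition = condition,
                 kernels = kernels),
            class = "aad_curve")
}

#' @export
print.aad_curve <- function(x, ...) {
  cat(sprintf("<aad_curve> %s\n", x$condition))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Cross-condition generalization
#'
#' Fits backward decoders on all trials of `train_cond` and classifies
#' decision windows of `test_cond` trials. With `train_cond == test_cond` the
#' evaluation is redirected to within-condition leave-one-trial-out CV.
#' Multiple sessions ("subjects") give mean accuracy and 10th/90th
#' percentiles.
#'
#' @param sessions one preprocessed session or a list of them.
#' @param train_cond,test_cond condition labels.
#' @param window decision-window length in seconds (35 by default).
#' @param lag_range,cfg,channels decoder settings.
#' @return list with `accuracy` (mean), `p10`, `p90`, `per_session`.
#' @export
cross_condition_eval <- function(sessions, train_cond, test_cond, window = 35,
                                 lag_range = c(-1, 1), cfg = boost_config(),
                                 channels = NULL) {
  if (inherits(sessions, "aad_session")) sessions <- list(sessions)
  accs <- vapply(sessions, function(sess) {
    if (train_cond == test_cond) {
      cv <- decision_window_curve(sess, train_cond, lengths = window,
                                  lag_range = lag_range, cfg = cfg,
                                  channels = channels)
      return(cv$curve$accuracy[1])
    }
    kern <- fit_decoder(sess, which(session_conditions(sess) == train_cond),
                        lag_range = lag_range, cfg = cfg, channels = channels)
    scores <- do.call(rbind, lapply(
      which(session_conditions(sess) == test_cond),
      function(i) score_reconstruction(kern, sess$trials[[i]], window)))
    classify_attention(scores)$accuracy
  }, 0)
  list(accuracy = mean(accs),
       p10 = as.numeric(quantile(accs, 0.1)),
       p90 = as.numeric(quantile(accs, 0.9)),
       per_session = accs)
}

#' Sliding optimal-lag analysis
#'
#' Fits short-lag forward and backward TRFs for sliding lag windows (default
#' length 45 ms, step 15 ms over -600..600 ms: 78 windows) and records the
#' cross-validated reconstruction/prediction correlation per window center,
#' separately per montage group and attended/ignored stream. Windows are
#' defined in continuous time; the lag-grid taps whose lag falls inside a
#' window are included (2-3 taps at 50 Hz). Forward correlations are averaged
#' across electrodes, giving one estimate per window.
#'
#' @param session preprocessed `aad_session`.
#' @param condition condition to scan.
#' @param directions subset of `c("backward", "forward")`.
#' @param montages named list of channel groups (default: the session's
#'   scalp and cEEGrid groups, skipping empty ones).
#' @param streams subset of `c("attended", "ignored")`.
#' @param window_ms,step_ms,range_ms scan geometry.
#' @param cfg a [boost_config()].
#' @return an `aad_lagscan`: data.frame (`center_ms`, `direction`, `montage`,
#'   `stream`, `rho`).
#' @export
optimal_lag_scan <- function(session, condition,
                             directions = c("backward", "forward"),
                             montages = NULL,
                             streams = c("attended", "ignored"),
                             window_ms = 45, step_ms = 15,
                             range_ms = c(-600, 600),
                             cfg = boost_config(partitions = 2)) {
  if (!isTRUE(session$preprocessed))
    stop("session must be preprocessed first", call. = FALSE)
  fs <- session$trials[[1]]$eeg$fs
  if (is.null(montages)) {
    montages <- list(scalp = session$montage$scalp,
                     ceegrid = session$montage$ceegrid)
    montages <- montages[vapply(montages, length, 0L) > 0]
  }
  starts <- seq(range_ms[1], range_ms[2] - window_ms, by = step_ms)
  centers <- starts + window_ms / 2
  folds <- make_folds(session, condition)
  all_lags <- seq(round(range_ms[1] / 1000 * fs), round(range_ms[2] / 1000 * fs))
  rows <- list()
  for (ci in seq_along(centers)) {
    cms <- centers[ci]
    taps <- all_lags[abs(all_lags / fs * 1000 - cms) < window_ms / 2]
    if (!length(taps)) next
    for (mi in seq_along(montages)) {
      chs <- montages[[mi]]
      for (stream in streams) {
        for (dirn in directions) {
          rho <- mean(vapply(folds, function(f) {
            test <- session$trials[[f$test]]
            feat_test <- composite_feature(test, stream)
            if (dirn == "backward") {
              kern <- fit_decoder(session, f$train, cfg = cfg, channels = chs,
                                  target = stream, lags = taps)
              safe_rho(reconstruct_backward(kern, eeg_subset(test$eeg, chs)),
                       feat_test)
            } else {
              ins <- lapply(session$trials[f$train], composite_feature,
                            role = stream)
              outs <- lapply(session$trials[f$train],
                             function(tr) eeg_subset(tr$eeg, chs))
              kern <- boosting_fit(ins, outs, cfg = cfg, direction = "forward",
                                   lags = taps)
              pred <- predict_forward(kern, feat_test)
              ytest <- eeg_subset(test$eeg, chs)
              mean(vapply(seq_along(chs), function(j)
                safe_rho(pred$values[, j], ytest$values[, j]), 0))
            }
          }, 0))
          rows[[length(rows) + 1L]] <- data.frame(
            center_ms = cms, direction = dirn,
            montage = names(montages)[mi], stream = stream, rho = rho)
        }
      }
    }
  }
  structure(do.call(rbind, rows), class = c("aad_lagscan", "data.frame"))
}

#' Peak of a lag scan
#'
#' @param scan an `aad_lagscan`.
#' @return data.frame with the argmax center per (direction, montage, stream).
#' @export
scan_peak <- function(scan) {
  sp <- split(scan, interaction(scan$direction, scan$montage, scan$stream,
                                drop = TRUE))
  do.call(rbind, lapply(sp, function(d) {
    d[which.max(d$rho), c("center_ms", "direction", "montage", "stream", "rho")]
  }))
}

#' Per-trial forward TRFs for a stream
#'
#' Fits one forward kernel per trial of a condition (feature of the given
#' role regressed onto the EEG), the unit entering group-level TRF
#' statistics.
#'
#' @param session preprocessed `aad_session`.
#' @param condition condition label.
#' @param role `"attended"` or `"ignored"`.
#' @param channels channel subset (default: scalp group).
#' @param lag_range lag range in seconds.
#' @param cfg a [boost_config()].
#' @return list of forward [trf_kernel()]s, one per trial.
#' @export
fit_forward_trfs <- function(session, condition, role = "attended",
                             channels = NULL, lag_range = c(-0.1, 0.5),
                             cfg = boost_config(partitions = 2)) {
  if (!isTRUE(session$preprocessed))
    stop("session must be preprocessed first", call. = FALSE)
  if (is.null(channels)) channels <- session$montage$scalp
  idx <- which(session_conditions(session) == condition)
  lapply(idx, function(i) {
    tr <- session$trials[[i]]
    boosting_fit(composite_feature(tr, role), eeg_subset(tr$eeg, channels),
                 lag_range = lag_range, cfg = cfg, direction = "forward")
  })
}
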