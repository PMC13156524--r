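# Synthetic two-talker listening sessions. The generator states a world with
# the statistical structure the analysis assumes: speech-like envelopes
# (gamma-renewal syllable pulses), ground-truth attended/ignored response
# kernels with P1/N1/P2 morphology, a trial protocol with three conditions
# (sustained / switching / conversation attention), spatially mixed 1/f
# background noise at a configurable SNR, and a control stream that is
# generated but never mixed into the EEG.

#' Simulation configuration
#'
#' @param n_scalp_channels,n_ceegrid_channels montage group sizes.
#' @param fs_raw raw simulation sampling rate (Hz); the preprocessing chain
#'   takes it down to 50 Hz.
#' @param trial_duration trial length in seconds.
#' @param trial_counts named counts for conditions SustAC, SwitAC, ConvAC.
#' @param switch_window_1,switch_window_2 intervals (s) the two SwitAC
#'   attention switches are drawn from, uniformly.
#' @param snr_db signal-to-noise ratio of the kernel-convolved stimulus
#'   response relative to the 1/f background, in dB (averaged over channels).
#' @param attention_gain amplitude of the ignored-stream response relative to
#'   the attended one, in (0, 1].
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_scalp_channels = 44, n_ceegrid_channels = 20,
                       fs_raw = 500, trial_duration = 180,
                       trial_counts = c(SustAC = 8, SwitAC = 8, ConvAC = 9),
                       switch_window_1 = c(35, 55),
                       switch_window_2 = c(125, 145),
                       snr_db = 0, attention_gain = 0.5, seed = 1L) {
  cfg <- list(n_scalp_channels = as.integer(n_scalp_channels),
              n_ceegrid_channels = as.integer(n_ceegrid_channels),
              fs_raw = fs_raw, trial_duration = trial_duration,
              trial_counts = trial_counts,
              switch_window_1 = switch_window_1,
              switch_window_2 = switch_window_2,
              snr_db = snr_db, attention_gain = attention_gain,
              seed = as.integer(seed))
  if (cfg$trial_duration <= 0) stop("trial_duration must be > 0", call. = FALSE)
  if (cfg$attention_gain <= 0 || cfg$attention_gain > 1)
    stop("attention_gain must be in (0, 1]", call. = FALSE)
  if (!all(c("SustAC", "SwitAC", "ConvAC") %in% names(cfg$trial_counts)))
    stop("trial_counts must name SustAC, SwitAC and ConvAC", call. = FALSE)
  if (any(cfg$trial_counts < 0)) stop("trial counts must be >= 0", call. = FALSE)
  if (cfg$switch_window_1[2] > cfg$switch_window_2[1])
    stop("switch_window_1 must entirely precede switch_window_2", call. = FALSE)
  if (cfg$trial_counts["SwitAC"] > 0 &&
      cfg$switch_window_2[2] >= cfg$trial_duration)
    stop("switch windows must lie inside the trial", call. = FALSE)
  if (cfg$n_scalp_channels < 1) stop("need at least one scalp channel", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Ground-truth response kernels and topography
#'
#' Builds the generative world for [synthesize_trial()]: attended and ignored
#' single-source TRFs with P1 (~40 ms), N1 (~100 ms) and P2 (~180 ms) bumps, a
#' smooth random per-channel topography (cEEGrid channels 6 dB weaker than
#' scalp), and the 1/f noise exponent. The ignored kernel shares the attended
#' morphology; the attended/ignored asymmetry is applied at mixing time via
#' the config's `attention_gain`, so ignored peak amplitudes never exceed
#' attended ones.
#'
#' @param cfg a [sim_config()].
#' @param seed seed for the topography draw.
#' @param peaks matrix-like peak spec rows `(latency_ms, amplitude, width_ms)`.
#' @return a `ground_truth` object.
#' @export
default_ground_truth <- function(cfg, seed = 1L,
                                 peaks = rbind(c(40, 0.6, 15),
                                               c(100, -1.0, 25),
                                               c(180, 0.7, 35))) {
  n_sc <- cfg$n_scalp_channels; n_ce <- cfg$n_ceegrid_channels
  kern <- synthesize_kernel(peaks, lag_range = c(0, 0.4), fs = cfg$fs_raw)
  topo <- with_seed(derive_seed(seed, key_from_string("topo")), {
    w <- abs(rnorm(n_sc + n_ce, mean = 1, sd = 0.15))
    pmax(w, 0.5)
  })
  if (n_ce > 0)
    topo[(n_sc + 1):(n_sc + n_ce)] <- 0.5 * topo[(n_sc + 1):(n_sc + n_ce)]
  structure(list(attended_kernel = kern, ignored_kernel = kern,
                 channel_topography = topo, noise_spectrum_exponent = 1),
            class = "ground_truth")
}

#' Synthesize a speech-like envelope
#'
#' A gamma-renewal pulse train (shape 2, mean inter-onset interval 250 ms,
#' i.e. a ~4 Hz syllable rate) with gamma-distributed pulse amplitudes,
#' convolved with a 150-ms raised-cosine window and modulated by a slow
#' positive drift. Nonnegative, with dominant spectral content in the 1-10 Hz
#' syllabic range; deterministic given the seed.
#'
#' @param duration length in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param seed integer seed.
#' @param mean_ioi mean inter-onset interval (s).
#' @param shape gamma shape of the renewal process.
#' @param smooth_s raised-cosine window length (s).
#' @return single-channel nonnegative [ts_block()].
#' @export
synthesize_envelope <- function(duration, fs, seed, mean_ioi = 0.25,
                                shape = 2, smooth_s = 0.15) {
  if (duration <= 0 || fs <= 0)
    stop("duration and fs must be positive", call. = FALSE)
  n <- round(duration * fs)
  with_seed(seed, {
    m <- ceiling(duration / mean_ioi * 3) + 20
    iois <- rgamma(m, shape = shape, scale = mean_ioi / shape)
    times <- cumsum(iois)
    times <- times[times < duration]
    amps <- rgamma(length(times), shape = 3, rate = 3)
    train <- numeric(n)
    idx <- pmin(floor(times * fs) + 1L, n)
    for (i in seq_along(idx)) train[idx[i]] <- train[idx[i]] + amps[i]
    L <- max(3L, round(smooth_s * fs))
    w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
    env <- convolve(train, rev(w), type = "open")[seq_len(n)]
    # slow positive drift, bounded away from zero
    ks <- runif(4, 0.02, 0.1)
    ph <- runif(4, 0, 2 * pi)
    tt <- (seq_len(n) - 1) / fs
    z <- rowSums(sapply(seq_along(ks), function(i) cos(2 * pi * ks[i] * tt + ph[i])))
    z <- (z - mean(z)) / max(sd(z), 1e-12)
    drift <- 0.8 + 0.4 * stats::pnorm(z)
    ts_block(pmax(env, 0) * drift, fs, "envelope")
  })
}

#' Synthesize a ground-truth TRF from Gaussian bumps
#'
#' The kernel is a sum of Gaussian bumps at the stated latencies (width =
#' Gaussian SD), truncated to exact zeros beyond four widths, scaled per
#' channel by the topography weights.
#'
#' @param peak_spec rows of `(latency_ms, amplitude, width_ms)`; may be empty.
#' @param lag_range `(t_min, t_max)` in seconds.
#' @param fs sampling rate (Hz) of the lag grid.
#' @param topography per-channel scale weights (default: one channel, unit).
#' @return a [trf_kernel()] (direction `"forward"`).
#' @export
synthesize_kernel <- function(peak_spec, lag_range, fs, topography = 1) {
  lags <- seq(round(lag_range[1] * fs), round(lag_range[2] * fs))
  tl <- lags / fs
  base <- numeric(length(lags))
  if (!is.null(peak_spec) && length(peak_spec)) {
    pk <- if (is.matrix(peak_spec)) peak_spec
          else if (is.list(peak_spec)) do.call(rbind, lapply(peak_spec, as.numeric))
          else matrix(as.numeric(peak_spec), ncol = 3, byrow = TRUE)
    for (i in seq_len(nrow(pk))) {
      lat <- pk[i, 1] / 1000; amp <- pk[i, 2]; wid <- pk[i, 3] / 1000
      if (lat < lag_range[1] || lat > lag_range[2])
        stop("peak latency outside lag_range", call. = FALSE)
      bump <- amp * exp(-0.5 * ((tl - lat) / wid)^2)
      bump[abs(tl - lat) > 4 * wid] <- 0
      base <- base + bump
    }
  }
  coef <- outer(base, as.numeric(topography))
  trf_kernel(coef, lags, fs, direction = "forward")
}

# spatially mixed 1/f^alpha background noise (n x n_ch), unit-order scale
one_over_f_noise <- function(n, fs, n_ch, alpha = 1) {
  n_src <- max(2L, min(n_ch, 16L))
  freqs <- c(1, seq_len(n - 1)) * fs / n  # index 1 = DC, reuse first bin scale
  scale_amp <- 1 / pmax(freqs, fs / n)^(alpha / 2)
  lat <- matrix(0, n, n_src)
  for (j in seq_len(n_src)) {
    X <- fft(rnorm(n)) * scale_amp
    lat[, j] <- Re(fft(X, inverse = TRUE)) / n
  }
  # smooth random spatial mixing so channels share correlated background
  W <- matrix(rnorm(n_src * n_ch), n_src, n_ch)
  if (n_ch > 2) {
    k <- c(0.25, 0.5, 1, 0.5, 0.25)
    W <- t(apply(W, 1, function(r) fft_conv_same(r, k / sum(k))))
  }
  noise <- lat %*% W
  noise / sd(noise)
}

apply_kernel_vec <- function(x, coef, lags) {
  out <- numeric(length(x))
  for (j in seq_along(lags)) {
    if (coef[j] != 0) out <- out + coef[j] * shift_zero(x, lags[j])
  }
  out
}

new_trial <- function(condition, streams, schedule, competing, control, eeg,
                      preprocessed = FALSE) {
  structure(list(condition = condition, streams = streams,
                 schedule = schedule, competing = competing,
                 control = control, eeg = eeg, preprocessed = preprocessed),
            class = "aad_trial")
}

#' @export
print.aad_trial <- function(x, ...) {
  cat(sprintf("<aad_trial> %s, %.0f s, %d EEG channels @ %g Hz, %d segments\n",
              x$condition, block_duration(x$eeg), ncol(x$eeg$values),
              x$eeg$fs, nrow(x$schedule)))
  invisible(x)
}

#' Synthesize one listening trial
#'
#' EEG = attended kernel * attended stream + `attention_gain` x ignored
#' kernel * competing stream (per the attention schedule) + spatially mixed
#' 1/f noise scaled to the configured SNR. SwitAC trials switch attention
#' twice, at times drawn uniformly from the config's switch windows; SustAC
#' and ConvAC have a single schedule segment. A control stream is generated
#' but never mixed into the EEG.
#'
#' @param cfg a [sim_config()].
#' @param truth a [default_ground_truth()] object (kernels at `cfg$fs_raw`).
#' @param condition `"SustAC"`, `"SwitAC"` or `"ConvAC"`.
#' @param seed integer seed.
#' @return an `aad_trial` with raw (unpreprocessed) EEG at `cfg$fs_raw`.
#' @export
synthesize_trial <- function(cfg, truth, condition, seed) {
  if (!condition %in% c("SustAC", "SwitAC", "ConvAC"))
    stop("unknown condition: ", condition, call. = FALSE)
  fs <- cfg$fs_raw; dur <- cfg$trial_duration
  n <- round(dur * fs)
  env_seed <- function(name) derive_seed(seed, key_from_string(name))

  if (condition == "ConvAC") {
    # two front talkers in alternating turns form the conversation mixture
    f1 <- synthesize_envelope(dur, fs, env_seed("front1"))$values[, 1]
    f2 <- synthesize_envelope(dur, fs, env_seed("front2"))$values[, 1]
    turns <- with_seed(env_seed("turns"), {
      tt <- cumsum(rgamma(ceiling(dur / 4) + 10, shape = 4, scale = 2))
      tt[tt < dur]
    })
    gate <- (findInterval((seq_len(n) - 1) / fs, turns) %% 2) == 0
    conv <- ifelse(gate, f1, f2)
    streams <- list(conv = ts_block(conv, fs, "conv"),
                    front1 = ts_block(f1, fs, "front1"),
                    front2 = ts_block(f2, fs, "front2"),
                    side = synthesize_envelope(dur, fs, env_seed("side")),
                    control = synthesize_envelope(dur, fs, env_seed("control")))
    competing <- c("conv", "side")
    schedule <- data.frame(start = 0, end = dur, stream = "conv",
                           stringsAsFactors = FALSE)
  } else {
    streams <- list(S1 = synthesize_envelope(dur, fs, env_seed("S1")),
                    S2 = synthesize_envelope(dur, fs, env_seed("S2")),
                    control = synthesize_envelope(dur, fs, env_seed("control")))
    competing <- c("S1", "S2")
    if (condition == "SustAC") {
      schedule <- data.frame(start = 0, end = dur, stream = "S1",
                             stringsAsFactors = FALSE)
    } else {
      sw <- with_seed(env_seed("switches"), {
        c(runif(1, cfg$switch_window_1[1], cfg$switch_window_1[2]),
          runif(1, cfg$switch_window_2[1], cfg$switch_window_2[2]))
      })
      schedule <- data.frame(start = c(0, sw[1], sw[2]),
                             end = c(sw[1], sw[2], dur),
                             stream = c("S1", "S2", "S1"),
                             stringsAsFactors = FALSE)
    }
  }

  # splice attended / ignored composite sources from the schedule
  att <- numeric(n); ign <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(schedule))) {
    sel <- tt >= schedule$start[i] & tt < schedule$end[i]
    a_id <- schedule$stream[i]
    i_id <- setdiff(competing, a_id)
    att[sel] <- streams[[a_id]]$values[sel, 1]
    ign[sel] <- streams[[i_id]]$values[sel, 1]
  }

  hk_a <- truth$attended_kernel; hk_i <- truth$ignored_kernel
  if (hk_a$fs != fs) stop("ground-truth kernels must be at cfg$fs_raw", call. = FALSE)
  clean1 <- apply_kernel_vec(att - mean(att), hk_a$coef[, 1], hk_a$lags) +
    cfg$attention_gain * apply_kernel_vec(ign - mean(ign), hk_i$coef[, 1], hk_i$lags)
  topo <- truth$channel_topography
  n_ch <- length(topo)
  clean <- outer(clean1, topo)

  noise <- with_seed(env_seed("noise"),
                     one_over_f_noise(n, fs, n_ch, truth$noise_spectrum_exponent))
  if (is.finite(cfg$snr_db)) {
    ps <- mean(colMeans(clean^2))
    pn <- mean(colMeans(noise^2))
    noise <- noise * sqrt(ps / pn / 10^(cfg$snr_db / 10))
  } else if (cfg$snr_db > 0) {
    noise <- noise * 0
  } else stop("snr_db = -Inf is not meaningful", call. = FALSE)

  mont <- default_montage(cfg$n_scalp_channels, cfg$n_ceegrid_channels)
  eeg <- ts_block(clean + noise, fs, montage_channels(mont))
  new_trial(condition, streams, schedule, competing, "control", eeg)
}

new_session <- function(trials, montage, cfg, truth, preprocessed = FALSE) {
  structure(list(trials = trials, montage = montage, cfg = cfg,
                 truth = truth, preprocessed = preprocessed),
            class = "aad_session")
}

#' @export
print.aad_session <- function(x, ...) {
  cond <- vapply(x$trials, function(t) t$condition, "")
  cat(sprintf("<aad_session> %d trials (%s)%s\n", length(x$trials),
              paste(sprintf("%s: %d", names(table(cond)), table(cond)),
                    collapse = ", "),
              if (x$preprocessed) ", preprocessed" else ", raw"))
  invisible(x)
}

session_conditions <- function(session)
  vapply(session$trials, function(t) t$condition, "")

#' Synthesize a full session
#'
#' Generates the configured number of trials per condition (defaults: 8
#' SustAC, 8 SwitAC, 9 ConvAC = 25 trials) with per-trial seeds derived
#' deterministically from the session seed.
#'
#' @param cfg a [sim_config()].
#' @param truth generative [default_ground_truth()]; built from `cfg` if NULL.
#' @param seed session seed (defaults to `cfg$seed`).
#' @return an `aad_session` with raw EEG.
#' @export
synthesize_session <- function(cfg, truth = NULL, seed = cfg$seed) {
  if (is.null(truth)) truth <- default_ground_truth(cfg, seed = seed)
  conds <- rep(c("SustAC", "SwitAC", "ConvAC"),
               times = cfg$trial_counts[c("SustAC", "SwitAC", "ConvAC")])
  trials <- lapply(seq_along(conds), function(i)
    synthesize_trial(cfg, truth, conds[i], derive_seed(seed, i)))
  new_session(trials, default_montage(cfg$n_scalp_channels, cfg$n_ceegrid_channels),
              cfg, truth)
}

#' Calibrated probe waveforms for feature tests
#'
#' @param kind `"pure_tone"`, `"am_noise"` or `"silence"`.
#' @param f0 tone frequency (Hz; pure_tone only).
#' @param fm amplitude-modulation rate (Hz; am_noise only).
#' @param duration,fs length (s) and sampling rate (Hz).
#' @param seed seed for the noise carrier.
#' @return single-channel [ts_block()].
#' @export
synthesize_probe_audio <- function(kind = c("pure_tone", "am_noise", "silence"),
                                   f0 = NULL, fm = NULL, duration = 1,
                                   fs = 44100, seed = 1L) {
  kind <- match.arg(kind)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- switch(kind,
    pure_tone = {
      if (is.null(f0)) stop("pure_tone needs f0", call. = FALSE)
      if (fs <= 2 * f0) stop("fs must exceed 2*f0 (aliasing)", call. = FALSE)
      sin(2 * pi * f0 * tt)
    },
    am_noise = {
      if (is.null(fm)) stop("am_noise needs fm", call. = FALSE)
      carrier <- with_seed(seed, rnorm(n))
      carrier * (1 + 0.9 * sin(2 * pi * fm * tt))
    },
    silence = numeric(n))
  ts_block(x, fs, "audio")
}

#' Preprocess every trial of a session
#'
#' Runs the canonical EEG chain on each trial's raw EEG and [prepare_feature()]
#' on each stimulus stream, yielding the 50-Hz normalized representation all
#' model fitting operates on.
#'
#' @param session raw `aad_session`.
#' @param fs_out output rate (Hz).
#' @param ... passed to [preprocess_eeg()].
#' @return preprocessed `aad_session`.
#' @export
preprocess_session <- function(session, fs_out = 50, ...) {
  if (isTRUE(session$preprocessed)) return(session)
  trials <- lapply(session$trials, function(tr) {
    eeg <- preprocess_eeg(tr$eeg, session$montage, fs_out = fs_out, ...)
    streams <- lapply(tr$streams, prepare_feature, fs_out = fs_out)
    new_trial(tr$condition, streams, tr$schedule, tr$competing, tr$control,
              eeg, preprocessed = TRUE)
  })
  new_session(trials, session$montage, session$cfg, session$truth,
              preprocessed = TRUE)
}
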