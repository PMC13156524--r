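# Small synthetic worlds shared across test files. Sizes are scaled down from
# the study protocol (fewer/shorter trials, fewer channels) to fit the test
# budget; generator parameters (SNR, attention gain, switch-window logic,
# kernel morphology) are the package defaults.

tiny_cfg <- function(duration = 30, n_scalp = 2, n_ceegrid = 0, fs_raw = 200,
                     counts = c(SustAC = 3, SwitAC = 0, ConvAC = 0),
                     snr_db = 10, gain = 0.5, seed = 1L,
                     sw1 = c(8, 12), sw2 = c(18, 22)) {
  sim_config(n_scalp_channels = n_scalp, n_ceegrid_channels = n_ceegrid,
             fs_raw = fs_raw, trial_duration = duration,
             trial_counts = counts, switch_window_1 = sw1,
             switch_window_2 = sw2, snr_db = snr_db, attention_gain = gain,
             seed = seed)
}

# memoized preprocessed session for the attention tests
.cache <- new.env(parent = emptyenv())

cached_session <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

fast_boost <- function(...) boost_config(partitions = 2, max_steps = 300, ...)

# hand-built preprocessed trial with fully controlled streams/EEG (bypasses
# the generator; used for exact scoring fixtures)
manual_trial <- function(att, ign, ctl, eeg, fs = 50, condition = "SustAC",
                         schedule = NULL, competing = c("S1", "S2")) {
  n <- length(att)
  if (is.null(schedule))
    schedule <- data.frame(start = 0, end = n / fs, stream = competing[1])
  streams <- list(ts_block(att, fs, competing[1]),
                  ts_block(ign, fs, competing[2]),
                  control = ts_block(ctl, fs, "control"))
  names(streams) <- c(competing, "control")
  aadtrf:::new_trial(condition, streams, schedule, competing, "control",
                     eeg, preprocessed = TRUE)
}
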