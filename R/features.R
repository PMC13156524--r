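# Speech-feature extraction: gammatone filterbank magnitudes on the ERB-rate
# scale, the broadband acoustic envelope (across-band sum), and acoustic
# onsets via an edge-detection operator, followed by the common
# bandpass/downsample/normalize preparation that both features and EEG share.

erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (1 + 0.00437 * f)

#' ERB-spaced gammatone center frequencies
#' @param n_bands number of bands.
#' @param fmin,fmax frequency range (Hz).
#' @keywords internal
gammatone_centers <- function(n_bands, fmin, fmax)
  erb_rate_inv(seq(erb_rate(fmin), erb_rate(fmax), length.out = n_bands))

# 4th-order gammatone impulse response, unit magnitude response at fc
gammatone_ir <- function(fs, fc, order = 4) {
  b <- 1.019 * erb_bandwidth(fc)
  t_max <- min(0.1, (order - 1 + log(1e5)) / (2 * pi * b))
  t <- seq(0, t_max, by = 1 / fs)
  ir <- t^(order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  gain <- abs(sum(ir * exp(-2i * pi * fc * t)))
  ir / gain
}

#' Gammatone filterbank decomposition
#'
#' Decomposes audio into nonnegative per-band magnitudes of 4th-order
#' gammatone filters with ERB-rate spaced center frequencies (default 128
#' bands between 80 and 15000 Hz), half-wave rectified, smoothed, and
#' decimated to 1-ms resolution (1000 Hz).
#'
#' @param audio single-channel [ts_block()].
#' @param n_bands number of bands.
#' @param fmin,fmax band range in Hz; `fmax` is clipped to Nyquist with a
#'   warning if necessary.
#' @param fs_out output rate of the magnitude representation (Hz).
#' @return a `gt_rep`: list with `values` (time x band), `band_centers`, `fs`.
#' @export
gammatone_decompose <- function(audio, n_bands = 128, fmin = 80, fmax = 15000,
                                fs_out = 1000) {
  stopifnot_block(audio, "audio")
  if (n_samples(audio) == 0) stop("empty audio", call. = FALSE)
  nyq <- audio$fs / 2
  if (fmax > nyq) {
    warning("fmax clipped to Nyquist (", nyq, " Hz)")
    fmax <- nyq * 0.999
  }
  x <- audio$values[, 1]
  centers <- gammatone_centers(n_bands, fmin, fmax)
  n <- length(x)
  m <- round(n * fs_out / audio$fs)
  vals <- matrix(0, m, n_bands)
  # envelope smoothing lowpass at the output Nyquist
  L <- fir_design_length(audio$fs, 0.2 * fs_out)
  h_lp <- fir_lowpass_taps(audio$fs, 0.45 * fs_out, L)
  nfft <- stats::nextn(n + max(L, 8192) - 1, 2)
  X <- fft(c(x, numeric(nfft - n)))
  Hlp <- fft(c(h_lp, numeric(nfft - L)))
  half_lp <- (L - 1) / 2
  for (b in seq_len(n_bands)) {
    ir <- gammatone_ir(audio$fs, centers[b])
    Hb <- fft(c(ir, numeric(nfft - length(ir))))
    y <- Re(fft(X * Hb, inverse = TRUE)) / nfft
    y <- pmax(y[seq_len(n)], 0)  # half-wave rectified band magnitude
    Ys <- fft(c(y, numeric(nfft - n))) * Hlp
    ys <- Re(fft(Ys, inverse = TRUE)) / nfft
    ys <- pmax(ys[(half_lp + 1):(half_lp + n)], 0)
    vals[, b] <- if (m == n) ys else fft_resample_vec(ys, m)
  }
  vals[vals < 0] <- 0
  structure(list(values = vals, band_centers = centers, fs = fs_out),
            class = "gt_rep")
}

#' @export
print.gt_rep <- function(x, ...) {
  cat(sprintf("<gt_rep> %d samples x %d bands @ %g Hz, %.0f-%.0f Hz\n",
              nrow(x$values), ncol(x$values), x$fs,
              min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

#' Broadband acoustic envelope
#'
#' Sum of the absolute values of the gammatone representation across
#' frequency bands.
#'
#' @param gt a `gt_rep` from [gammatone_decompose()].
#' @return single-channel nonnegative [ts_block()] (name `"envelope"`).
#' @export
acoustic_envelope <- function(gt) {
  if (!inherits(gt, "gt_rep")) stop("gt must be a gt_rep", call. = FALSE)
  out <- ts_block(rowSums(abs(gt$values)), gt$fs, "envelope")
  attr(out, "feature") <- "envelope"
  out
}

#' Acoustic onsets (edge detection)
#'
#' Per band: compress the magnitude (`log(1 + k x) / log(1 + k)`, so a unit
#' step yields a unit-order edge), subtract a delayed low-passed copy,
#' half-wave rectify, then sum across bands. Emphasizes rapid amplitude
#' increases; the constants are tunables since published edge-detector
#' settings vary.
#'
#' @param gt a `gt_rep`.
#' @param delay_ms delay of the reference copy (ms, > 0).
#' @param lowpass_hz lowpass applied to the delayed copy (Hz).
#' @param k compression constant.
#' @param compression `"log"` (default) or `"none"`.
#' @return single-channel nonnegative [ts_block()] (name `"onset"`).
#' @export
acoustic_onsets <- function(gt, delay_ms = 10, lowpass_hz = 30, k = 100,
                            compression = c("log", "none")) {
  if (!inherits(gt, "gt_rep")) stop("gt must be a gt_rep", call. = FALSE)
  compression <- match.arg(compression)
  if (delay_ms <= 0) stop("delay must be positive", call. = FALSE)
  v <- gt$values
  z <- if (compression == "log") log1p(k * v) / log1p(k) else v
  d <- round(delay_ms / 1000 * gt$fs)
  zd <- shift_zero_mat(z, d)
  L <- fir_design_length(gt$fs, max(lowpass_hz * 0.5, 5))
  h <- fir_lowpass_taps(gt$fs, lowpass_hz, L)
  zd <- fft_conv_same(zd, h)
  edges <- pmax(z - zd, 0)
  out <- ts_block(rowSums(edges), gt$fs, "onset")
  attr(out, "feature") <- "onset"
  out
}

#' Prepare a feature or synthetic envelope for model fitting
#'
#' Zero-phase FIR bandpass 1-20 Hz, downsample to 50 Hz, z-score. Both
#' gammatone-derived features and synthetic envelopes enter the TRF stage
#' through this function.
#'
#' @param f single-channel [ts_block()] at >= 50 Hz.
#' @param band bandpass edges (Hz).
#' @param fs_out output rate (Hz).
#' @return normalized single-channel `ts_block` at `fs_out`, with
#'   `attr(, "normalized") = TRUE`.
#' @export
prepare_feature <- function(f, band = c(1, 20), fs_out = 50) {
  stopifnot_block(f, "f")
  if (f$fs < fs_out)
    stop("input sampling rate below the target rate", call. = FALSE)
  x <- fir_bandpass(f, band[1], band[2])
  x <- resample(x, fs_out)
  x <- normalize_channels(x)
  attr(x, "normalized") <- TRUE
  attr(x, "feature") <- attr(f, "feature")
  x
}
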