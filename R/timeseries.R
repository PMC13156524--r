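#' Uniformly sampled multichannel time series
#'
#' The basic signal carrier used throughout the package, holding EEG channels
#' as well as single-channel stimulus features: a numeric matrix with one
#' column per channel, a sampling rate, and channel labels.
#'
#' @param values numeric vector (one channel) or matrix (time x channels).
#' @param fs sampling rate in Hz.
#' @param channels optional character vector of channel labels.
#' @return An object of class `ts_block`.
#' @export
ts_block <- function(values, fs, channels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  if (length(channels) != ncol(values))
    stop("channel labels do not match the number of columns", call. = FALSE)
  colnames(values) <- channels
  structure(list(values = values, fs = as.numeric(fs),
                 channels = as.character(channels)),
            class = "ts_block")
}

#' @export
print.ts_block <- function(x, ...) {
  cat(sprintf("<ts_block> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$values), ncol(x$values), x$fs, n_samples(x) / x$fs))
  invisible(x)
}

n_samples <- function(x) nrow(x$values)

block_duration <- function(x) nrow(x$values) / x$fs

stopifnot_block <- function(x, what = "x") {
  if (!inherits(x, "ts_block"))
    stop(sprintf("%s must be a ts_block", what), call. = FALSE)
  invisible(x)
}

#' Zero-padded sample shift
#'
#' Returns `out[k] = v[k - s]` with zeros where the index falls outside the
#' signal: the edge policy used for all TRF convolutions.
#'
#' @param v numeric vector.
#' @param s integer shift in samples (positive delays the signal).
#' @keywords internal
shift_zero <- function(v, s) {
  n <- length(v)
  out <- numeric(n)
  if (s >= n || -s >= n) return(out)
  if (s >= 0) out[(s + 1L):n] <- v[1L:(n - s)]
  else out[1L:(n + s)] <- v[(1L - s):n]
  out
}

shift_zero_mat <- function(m, s) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  if (s >= n || -s >= n) return(out)
  if (s >= 0) out[(s + 1L):n, ] <- m[1L:(n - s), , drop = FALSE]
  else out[1L:(n + s), ] <- m[(1L - s):n, , drop = FALSE]
  out
}
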