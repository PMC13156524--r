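# Temporal response function core. A TRF h_{l,i} maps a stimulus feature to
# EEG (forward: y_i(k) = sum_l h_{l,i} x(k - l)) or EEG to the feature
# (backward: x(k) = sum_i sum_l h_{l,i} y_i(k + l)) over a uniform lag grid.
# Estimation is greedy coordinate boosting on a Hamming basis with
# mean-absolute-error objective and validation-based selective stopping.

#' TRF kernel
#'
#' Coefficients over a uniform lag grid, one column per channel (EEG channels
#' for forward kernels; EEG input channels for backward kernels), together
#' with the basis metadata and estimated basis weights when fitted.
#'
#' @param coef numeric matrix, lags x channels.
#' @param lags integer lags in samples (uniform, spacing 1).
#' @param fs sampling rate (Hz) of the lag grid.
#' @param direction `"forward"` or `"backward"`.
#' @param basis optional [make_basis()] metadata.
#' @param weights optional basis-weight matrix (channels x basis functions).
#' @param channels optional channel labels.
#' @param fit optional fit log.
#' @return object of class `trf_kernel`.
#' @export
trf_kernel <- function(coef, lags, fs, direction = c("forward", "backward"),
                       basis = NULL, weights = NULL, channels = NULL,
                       fit = NULL) {
  direction <- match.arg(direction)
  coef <- as.matrix(coef)
  lags <- as.integer(lags)
  if (nrow(coef) != length(lags)) stop("coef/lag mismatch", call. = FALSE)
  if (length(lags) > 1 && !all(diff(lags) == diff(lags)[1]))
    stop("lag grid must be uniform", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(coef)))
  structure(list(coef = coef, lags = lags, fs = fs, direction = direction,
                 basis = basis, weights = weights, channels = channels,
                 fit = fit),
            class = "trf_kernel")
}

#' @export
print.trf_kernel <- function(x, ...) {
  cat(sprintf("<trf_kernel> %s, %d lags [%g, %g] s @ %g Hz, %d channels\n",
              x$direction, length(x$lags), min(x$lags) / x$fs,
              max(x$lags) / x$fs, x$fs, ncol(x$coef)))
  invisible(x)
}

kernel_lag_seconds <- function(k) k$lags / k$fs

#' Hamming basis for TRF estimation
#'
#' One Hamming window of the given width is centered on each element of the
#' lag grid (unit peak amplitude), so the estimated TRF is a weighted sum
#' `h_l = sum_p w_p phi_p(l)` smoothed over roughly the window width. At
#' 50 Hz and 50-ms width each window covers 3 grid points.
#'
#' @param lag_count number of lag-grid elements P.
#' @param width window width in ms (>= one sample).
#' @param spacing grid spacing in ms (defaults to `1000/fs`).
#' @param fs sampling rate (Hz).
#' @return a `basis_set`: list with the P x P basis matrix (rows = lags,
#'   columns = basis functions), the centered prototype taps, width, spacing.
#' @export
make_basis <- function(lag_count, width = 50, spacing = 1000 / fs, fs = 50) {
  if (width < 1000 / fs)
    stop("basis width smaller than one sample", call. = FALSE)
  dt <- spacing  # ms between grid points
  max_off <- floor((width / 2 - 1e-9) / dt)
  off <- (-max_off):max_off
  proto <- 0.54 + 0.46 * cos(2 * pi * (off * dt) / width)
  proto[abs(off * dt) >= width / 2] <- 0
  proto <- proto / max(proto)  # unit peak
  B <- matrix(0, lag_count, lag_count)
  for (p in seq_len(lag_count)) {
    idx <- p + off
    ok <- idx >= 1 & idx <= lag_count
    B[idx[ok], p] <- proto[ok]
  }
  structure(list(matrix = B, proto = proto, proto_offsets = off,
                 count = lag_count, width = width, spacing = dt),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> P = %d Hamming windows, width %g ms, spacing %g ms\n",
              x$count, x$width, x$spacing))
  invisible(x)
}

#' Predict EEG from a stimulus feature (forward model)
#'
#' `y_i(k) = sum_l h_{l,i} x(k - l)`, zero-padded at the edges.
#'
#' @param kernel forward [trf_kernel()].
#' @param feature single-channel [ts_block()] at the kernel's rate.
#' @return multichannel `ts_block` of predicted EEG.
#' @export
predict_forward <- function(kernel, feature) {
  stopifnot_block(feature, "feature")
  if (kernel$direction != "forward") stop("kernel is not forward", call. = FALSE)
  if (kernel$fs != feature$fs) stop("sampling rate mismatch", call. = FALSE)
  x <- feature$values[, 1]
  n <- length(x)
  XS <- matrix(0, n, length(kernel$lags))
  for (j in seq_along(kernel$lags)) XS[, j] <- shift_zero(x, kernel$lags[j])
  ts_block(XS %*% kernel$coef, kernel$fs, kernel$channels)
}

#' Reconstruct a stimulus feature from EEG (backward model)
#'
#' `x(k) = sum_i sum_l h_{l,i} y_i(k + l)`, zero-padded at the edges.
#'
#' @param kernel backward [trf_kernel()].
#' @param eeg multichannel [ts_block()]; channel count must match the kernel.
#' @return single-channel `ts_block` of the reconstructed feature.
#' @export
reconstruct_backward <- function(kernel, eeg) {
  stopifnot_block(eeg, "eeg")
  if (kernel$direction != "backward") stop("kernel is not backward", call. = FALSE)
  if (ncol(eeg$values) != ncol(kernel$coef))
    stop("channel count mismatch", call. = FALSE)
  if (kernel$fs != eeg$fs) stop("sampling rate mismatch", call. = FALSE)
  n <- nrow(eeg$values)
  out <- numeric(n)
  for (j in seq_along(kernel$lags)) {
    cj <- kernel$coef[j, ]
    if (all(cj == 0)) next
    out <- out + shift_zero_mat(eeg$values, -kernel$lags[j]) %*% cj
  }
  ts_block(out, kernel$fs, "reconstruction")
}

#' Pearson correlation coefficient
#'
#' Direct evaluation of the product-moment formula; symmetric and invariant
#' to affine rescaling of either argument.
#'
#' @param a,b numeric vectors of equal length >= 2 (or single-channel
#'   `ts_block`s).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (inherits(a, "ts_block")) a <- a$values[, 1]
  if (inherits(b, "ts_block")) b <- b$values[, 1]
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need at least two samples", call. = FALSE)
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0) {
    cond <- structure(class = c("aadtrf_zero_variance", "error", "condition"),
                      list(message = "undefined correlation: zero variance",
                           call = sys.call(-1)))
    stop(cond)
  }
  sum(da * db) / sqrt(va * vb)
}

#' Boosting configuration
#'
#' @param step_size increment per boosting step, in units of target SD
#'   (applied to inputs at their own scale).
#' @param partitions number of contiguous inner validation partitions (>= 2);
#'   each serves once as validation and the resulting kernels are averaged.
#' @param patience steps without inner-validation improvement before stopping.
#' @param objective only `"MAE"` is defined.
#' @param max_steps hard cap on boosting steps per fit.
#' @param seed unused placeholder (boosting is deterministic).
#' @return a `boost_config` list.
#' @export
boost_config <- function(step_size = 0.005, partitions = 4, patience = 20,
                         objective = "MAE", max_steps = 10000, seed = NULL) {
  if (step_size <= 0) stop("step_size must be > 0", call. = FALSE)
  if (partitions < 2) stop("need >= 2 partitions", call. = FALSE)
  structure(list(step_size = step_size, partitions = as.integer(partitions),
                 patience = as.integer(patience),
                 objective = match.arg(objective, "MAE"),
                 max_steps = as.integer(max_steps), seed = seed),
            class = "boost_config")
}

as_block_list <- function(x) {
  if (inherits(x, "ts_block")) list(x) else x
}

# basis-smoothed concatenation of input segments; returns list(S, seg_starts)
smooth_concat <- function(blocks, basis) {
  proto <- basis$proto; off <- basis$proto_offsets
  mats <- lapply(blocks, function(b) {
    v <- b$values
    out <- matrix(0, nrow(v), ncol(v))
    for (i in seq_along(off)) {
      if (proto[i] == 0) next
      out <- out + proto[i] * shift_zero_mat(v, off[i])
    }
    out
  })
  ns <- vapply(mats, nrow, 0L)
  list(S = do.call(rbind, mats),
       seg_starts = as.integer(cumsum(c(0L, ns[-length(ns)]))))
}

# core boosting over an explicit lag vector (samples); single target channel
boost_fit_single <- function(S, y, seg_starts, lags, direction, cfg) {
  N <- nrow(S); C <- ncol(S); P <- length(lags)
  shifts <- if (direction == "forward") as.integer(lags) else as.integer(-lags)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) {
    warning("degenerate (constant) target: returning zero kernel")
    return(list(weights = matrix(0, C, P), val_mae = NA_real_, steps = 0L))
  }
  delta <- cfg$step_size * sdy
  bounds <- floor(seq(0, N, length.out = cfg$partitions + 1))
  Ws <- vector("list", cfg$partitions)
  val <- numeric(cfg$partitions)
  steps <- 0L
  for (j in seq_len(cfg$partitions)) {
    f <- boost_fit_cpp(S, y, shifts, seg_starts,
                       as.integer(bounds[j]), as.integer(bounds[j + 1]),
                       delta, cfg$patience, cfg$max_steps)
    Ws[[j]] <- f$weights
    val[j] <- f$val_mae
    steps <- steps + f$steps
  }
  W <- Reduce(`+`, Ws) / cfg$partitions
  list(weights = W, val_mae = val, steps = steps)
}

#' Fit a TRF by sparse boosting
#'
#' Greedy coordinate boosting over (basis function, channel) pairs: at each
#' step the single basis weight whose +/- `step_size` increment most reduces
#' the inner-training mean absolute error is updated; fitting stops per
#' regression problem when the inner-validation MAE has not improved for
#' `patience` steps, and the kernel at the validation minimum is kept
#' (selective stopping). The training data are split into `partitions`
#' contiguous inner folds, each serving once as validation; the returned
#' kernel is the average over partitions, expressed exactly as a weighted sum
#' of the Hamming basis. Weights never selected stay exactly zero, giving
#' sparse kernels.
#'
#' @param inputs a [ts_block()] or list of blocks (trials/segments). For
#'   forward fitting this is the (single-channel) stimulus feature; for
#'   backward fitting the multichannel EEG.
#' @param targets a `ts_block` or list matching `inputs`: EEG (forward) or
#'   the feature to reconstruct (backward). Forward fitting with multichannel
#'   targets fits each EEG channel as its own regression problem.
#' @param lag_range `(t_min, t_max)` in seconds; the lag grid is
#'   `round(t_min*fs):round(t_max*fs)` samples.
#' @param basis a [make_basis()]; built with 50-ms windows by default.
#' @param cfg a [boost_config()].
#' @param direction `"forward"` or `"backward"`.
#' @param lags optional explicit lag vector in samples (overrides
#'   `lag_range`; used by the sliding optimal-lag analysis).
#' @return a fitted [trf_kernel()].
#' @export
boosting_fit <- function(inputs, targets, lag_range = c(-1, 1), basis = NULL,
                         cfg = boost_config(),
                         direction = c("forward", "backward"), lags = NULL) {
  direction <- match.arg(direction)
  inputs <- as_block_list(inputs); targets <- as_block_list(targets)
  if (length(inputs) != length(targets))
    stop("inputs/targets segment counts differ", call. = FALSE)
  fs <- inputs[[1]]$fs
  for (i in seq_along(inputs)) {
    if (inputs[[i]]$fs != targets[[i]]$fs)
      stop("sampling rate mismatch", call. = FALSE)
    if (n_samples(inputs[[i]]) != n_samples(targets[[i]]))
      stop("inputs and targets must have equal durations", call. = FALSE)
  }
  if (is.null(lags)) lags <- seq(round(lag_range[1] * fs), round(lag_range[2] * fs))
  lags <- as.integer(lags)
  P <- length(lags)
  if (is.null(basis)) basis <- make_basis(P, width = 50, spacing = 1000 / fs, fs = fs)
  if (basis$count != P) stop("basis size does not match lag grid", call. = FALSE)

  sc <- smooth_concat(inputs, basis)
  tv <- do.call(rbind, lapply(targets, function(b) b$values))
  n_out <- ncol(tv)
  if (direction == "backward" && n_out != 1)
    stop("backward fitting needs a single-channel target", call. = FALSE)
  if (direction == "forward" && ncol(sc$S) != 1)
    stop("forward fitting uses a single-channel input feature", call. = FALSE)

  coef <- matrix(0, P, n_out)
  Wout <- matrix(0, if (direction == "forward") n_out else ncol(sc$S), P)
  vals <- list(); steps <- 0L
  if (direction == "forward") {
    for (i in seq_len(n_out)) {
      f <- boost_fit_single(sc$S, tv[, i], sc$seg_starts, lags, direction, cfg)
      coef[, i] <- basis$matrix %*% as.numeric(f$weights[1, ])
      Wout[i, ] <- f$weights[1, ]
      vals[[i]] <- f$val_mae; steps <- steps + f$steps
    }
    channels <- targets[[1]]$channels
  } else {
    f <- boost_fit_single(sc$S, tv[, 1], sc$seg_starts, lags, direction, cfg)
    coef <- basis$matrix %*% t(f$weights)
    Wout <- f$weights
    vals[[1]] <- f$val_mae; steps <- f$steps
    channels <- inputs[[1]]$channels
  }
  trf_kernel(coef, lags, fs, direction = direction, basis = basis,
             weights = Wout, channels = channels,
             fit = list(val_mae = vals, steps = steps, cfg = cfg))
}
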