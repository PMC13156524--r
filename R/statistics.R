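# Group-level statistics on TRFs and scalar metrics: Gaussian kernel
# smoothing, mass-univariate t maps, threshold-free cluster enhancement with
# max-statistic permutation control, Benjamini-Hochberg adjustment, and
# paired t tests for correlation metrics.

kernels_to_array <- function(kernels) {
  if (is.array(kernels) && length(dim(kernels)) == 3) return(kernels)
  if (is.matrix(kernels)) {  # n x points, single channel
    return(array(kernels, dim = c(nrow(kernels), ncol(kernels), 1L)))
  }
  stopifnot(is.list(kernels), length(kernels) >= 1)
  mats <- lapply(kernels, function(k) if (inherits(k, "trf_kernel")) k$coef else as.matrix(k))
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stop("kernel shapes differ", call. = FALSE)
  arr <- array(0, dim = c(length(mats), d[1], d[2]))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' Gaussian smoothing of a TRF along the lag axis
#'
#' Convolution with a Gaussian of the given full width at half maximum
#' (FWHM), with partial-window renormalization at the edges so constants pass
#' unchanged and interior mass is preserved.
#'
#' @param trf a [trf_kernel()].
#' @param width Gaussian width in ms, interpreted as FWHM (set
#'   `width_is_fwhm = FALSE` to interpret it as the SD).
#' @param width_is_fwhm flag, see above.
#' @return smoothed `trf_kernel`.
#' @export
smooth_trf <- function(trf, width = 50, width_is_fwhm = TRUE) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  sd_s <- if (width_is_fwhm) width / 1000 / (2 * sqrt(2 * log(2))) else width / 1000
  r <- max(1L, ceiling(4 * sd_s * trf$fs))
  tt <- (-r):r / trf$fs
  g <- exp(-0.5 * (tt / sd_s)^2)
  g <- g / sum(g)
  n <- nrow(trf$coef)
  sm <- matrix(0, n, ncol(trf$coef))
  wsum <- numeric(n)
  for (i in seq_along(tt)) {
    off <- i - r - 1L
    sm <- sm + g[i] * shift_zero_mat(trf$coef, off)
    lo <- max(1L, 1L + off); hi <- min(n, n + off)
    wsum[lo:hi] <- wsum[lo:hi] + g[i]
  }
  sm <- sm / wsum
  trf_kernel(sm, trf$lags, trf$fs, direction = trf$direction,
             basis = trf$basis, channels = trf$channels)
}

new_stat_map <- function(t, lags = NULL, fs = NULL, df = NULL, tfce = NULL,
                         p = NULL, alpha = NULL, params = list()) {
  structure(list(t = as.matrix(t), lags = lags, fs = fs, df = df,
                 tfce = tfce, p = p,
                 mask = if (!is.null(p) && !is.null(alpha)) p < alpha else NULL,
                 alpha = alpha, params = params),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d x %d points, max |t| = %.2f%s\n",
              nrow(x$t), ncol(x$t), max(abs(x$t)),
              if (!is.null(x$p)) sprintf(", %d significant at alpha = %g",
                                         sum(x$mask), x$alpha) else ""))
  invisible(x)
}

#' Mass-univariate t map over (lag, channel) points
#'
#' Pointwise two-sample t statistics (pooled variance) between two groups of
#' TRFs, or paired/one-sample t on the per-unit differences with
#' `paired = TRUE`.
#'
#' @param group_a,group_b lists of [trf_kernel()]s (or n x lag x channel
#'   arrays / n x points matrices) with matching shapes; each element is one
#'   unit (subject or trial).
#' @param paired flag; paired tests require equal group sizes.
#' @return a `stat_map` holding the t matrix and degrees of freedom.
#' @export
mass_univariate_t <- function(group_a, group_b, paired = FALSE) {
  a <- kernels_to_array(group_a); b <- kernels_to_array(group_b)
  if (!identical(dim(a)[-1], dim(b)[-1])) stop("shape mismatch", call. = FALSE)
  na <- dim(a)[1]; nb <- dim(b)[1]
  if (na < 2 || nb < 2) stop("need >= 2 kernels per group", call. = FALSE)
  pts <- prod(dim(a)[-1])
  am <- matrix(a, na, pts); bm <- matrix(b, nb, pts)
  if (paired) {
    if (na != nb) stop("paired test needs equal group sizes", call. = FALSE)
    d <- am - bm
    mu <- colMeans(d)
    s <- apply(d, 2, sd)
    t <- mu / (s / sqrt(na))
    df <- na - 1
  } else {
    va <- apply(am, 2, var); vb <- apply(bm, 2, var)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    t <- (colMeans(am) - colMeans(bm)) / (sp * sqrt(1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t[!is.finite(t)] <- 0
  is_klist <- is.list(group_a) && inherits(group_a[[1]], "trf_kernel")
  lag1 <- if (is_klist) group_a[[1]]$lags else NULL
  fs1 <- if (is_klist) group_a[[1]]$fs else NULL
  new_stat_map(matrix(t, dim(a)[2], dim(a)[3]), lags = lag1, fs = fs1, df = df)
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' `TFCE(p) = sum_h extent_h(p)^E * h^H * dh` for thresholds `h` up to the
#' point's |t|, computed separately for positive and negative t. Adjacency is
#' along the lag axis within each channel. The stored map is the nonnegative
#' enhancement magnitude; signs are recoverable from the t map.
#'
#' @param smap a `stat_map` (from [mass_univariate_t()]) or a bare t matrix.
#' @param E,H extent and height exponents (Smith-Nichols defaults 0.5 and 2).
#' @param dh threshold step; defaults to `max(|t|)/100`.
#' @return the `stat_map` with the `tfce` field filled.
#' @export
tfce_enhance <- function(smap, E = 0.5, H = 2, dh = NULL) {
  if (!inherits(smap, "stat_map")) smap <- new_stat_map(smap)
  tmax <- max(abs(smap$t))
  if (is.null(dh)) dh <- if (tmax > 0) tmax / 100 else 1
  if (E <= 0 || H <= 0 || dh <= 0) stop("E, H, dh must be > 0", call. = FALSE)
  smap$tfce <- tfce_cpp(smap$t, E, H, dh)
  smap$params <- modifyList(smap$params, list(E = E, H = H, dh = dh))
  smap
}

#' Permutation p-values for TFCE maps
#'
#' Builds the null distribution of the maximum TFCE statistic under label
#' exchange (independent groups) or sign flips of the paired differences, and
#' assigns each point `p = (1 + #{null max >= observed}) / (1 + n_perm)`:
#' family-wise control over all (lag, channel) points.
#'
#' @param group_a,group_b as in [mass_univariate_t()].
#' @param paired flag.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draw.
#' @param E,H,dh TFCE parameters; `dh` defaults to `max(|t_obs|)/100` and is
#'   held fixed across permutations.
#' @param alpha significance level for the returned mask.
#' @return a `stat_map` with `t`, `tfce`, `p`, `mask` and the permutation
#'   parameters.
#' @export
permutation_pvalues <- function(group_a, group_b, paired = FALSE,
                                n_perm = 1000, seed = 1L, E = 0.5, H = 2,
                                dh = NULL, alpha = 0.05) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  a <- kernels_to_array(group_a); b <- kernels_to_array(group_b)
  na <- dim(a)[1]; nb <- dim(b)[1]
  nlag <- dim(a)[2]; nch <- dim(a)[3]; pts <- nlag * nch
  if (paired && na != nb) stop("paired permutation needs equal sizes", call. = FALSE)
  enough <- if (paired) na >= 5 else choose(na + nb, na) >= 20
  if (min(na, nb) < 2 || !enough)
    stop("too few exchangeable units for a permutation null", call. = FALSE)
  obs <- mass_univariate_t(group_a, group_b, paired = paired)
  tmax <- max(abs(obs$t))
  if (is.null(dh)) dh <- if (tmax > 0) tmax / 100 else 1
  obs <- tfce_enhance(obs, E = E, H = H, dh = dh)

  am <- matrix(a, na, pts); bm <- matrix(b, nb, pts)
  tnull <- with_seed(seed, {
    if (paired) {
      d <- am - bm
      msq <- colMeans(d * d)
      signs <- matrix(sample(c(-1, 1), n_perm * na, replace = TRUE), n_perm, na)
      mu <- (signs %*% d) / na
      vr <- sweep(-mu^2, 2, msq, "+") * na / (na - 1)
      vr[vr < 1e-300] <- 1e-300
      t(mu / sqrt(vr / na))  # pts x n_perm
    } else {
      x <- rbind(am, bm); n <- na + nb
      sel <- matrix(0, n_perm, n)
      for (q in seq_len(n_perm)) sel[q, sample.int(n, na)] <- 1
      sx <- colSums(x); sxx <- colSums(x * x)
      sa <- sel %*% x
      saa <- sel %*% (x * x)
      ma <- sa / na; mb <- sweep(-sa, 2, sx, "+") / nb
      ssa <- saa - na * ma^2
      ssb <- sweep(-saa, 2, sxx, "+") - nb * mb^2
      sp <- sqrt((ssa + ssb) / (n - 2))
      sp[sp < 1e-150] <- 1e-150
      t((ma - mb) / (sp * sqrt(1 / na + 1 / nb)))
    }
  })
  null_max <- tfce_max_cpp(tnull, nlag, E, H, dh)
  pv <- (1 + colSums(outer(null_max, as.numeric(obs$tfce), ">=") * 1)) / (1 + n_perm)
  obs$p <- matrix(pv, nlag, nch)
  obs$alpha <- alpha
  obs$mask <- obs$p < alpha
  obs$params <- modifyList(obs$params,
                           list(n_perm = n_perm, seed = seed, paired = paired))
  obs
}

#' Benjamini-Hochberg step-up rule
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q false-discovery rate.
#' @return logical rejection mask in the original order.
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

#' Paired t test on per-subject metrics
#'
#' Classical paired t on the differences, two-sided p-value.
#'
#' @param metric_a,metric_b numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_metric_test <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("length mismatch", call. = FALSE)
  n <- length(metric_a)
  if (n < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- metric_a - metric_b
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
    stop("degenerate variance in paired differences", call. = FALSE)
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), df = n - 1), df = n - 1,
       mean_diff = mean(d))
}

#' Export a stat map as a tidy table
#'
#' @param smap a `stat_map`.
#' @return data.frame (`lag_ms`, `channel`, `t`, `tfce`, `p`, `significant`).
#' @export
stat_map_table <- function(smap) {
  nlag <- nrow(smap$t); nch <- ncol(smap$t)
  lag_ms <- if (!is.null(smap$lags) && !is.null(smap$fs))
    smap$lags / smap$fs * 1000 else seq_len(nlag)
  data.frame(lag_ms = rep(lag_ms, nch),
             channel = rep(seq_len(nch), each = nlag),
             t = as.numeric(smap$t),
             tfce = if (!is.null(smap$tfce)) as.numeric(smap$tfce) else NA_real_,
             p = if (!is.null(smap$p)) as.numeric(smap$p) else NA_real_,
             significant = if (!is.null(smap$mask)) as.logical(smap$mask) else NA)
}
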