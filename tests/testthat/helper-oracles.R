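# Independent oracles used to pin expected values.

# Ordinary least-squares deconvolution: the closed-form reference estimator
# for a forward TRF on a lag grid (kept out of the package API on purpose).
ols_deconv <- function(x, y, lags) {
  X <- sapply(lags, function(l) aadtrf:::shift_zero(x, l))
  qr.solve(crossprod(X), crossprod(X, y))
}

# Brute-force TFCE: literal evaluation of the enhancement sum on a
# (lag x channel) map, adjacency along lags within channel.
tfce_brute <- function(t, E, H, dh) {
  out <- array(0, dim(t))
  for (ch in seq_len(ncol(t))) {
    for (sgn in c(1, -1)) {
      v <- sgn * t[, ch]
      hmax <- max(v)
      if (hmax <= 0) next
      hs <- seq(dh, hmax + 1e-12, by = dh)
      for (h in hs) {
        above <- v >= h
        r <- rle(above)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (j in which(r$values)) {
          idx <- starts[j]:ends[j]
          out[idx, ch] <- out[idx, ch] + r$lengths[j]^E * h^H * dh
        }
      }
    }
  }
  out
}

rms <- function(v) sqrt(mean(v^2))

# run code under a local seed without touching the session RNG state
with_seed_test <- function(seed, code) aadtrf:::with_seed(seed, code)

# steady-state gain of a filtered sinusoid, ignoring edge transients
interior_ratio <- function(y, x, frac = 0.25) {
  n <- length(x)
  idx <- floor(n * frac):ceiling(n * (1 - frac))
  rms(y[idx]) / rms(x[idx])
}
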