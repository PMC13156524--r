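# Seed plumbing. All generators are pure functions of (arguments, seed): they
# run under a locally set seed and restore the caller's RNG state afterwards.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds via a Lehmer step (MINSTD); keeps values in
# [1, 2^31 - 2] so they are always valid R integer seeds.
derive_seed <- function(seed, key) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (k in as.numeric(key)) {
    s <- (48271 * ((s + k) %% m)) %% m
    if (s == 0) s <- 1
  }
  as.integer(s)
}

key_from_string <- function(x) sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
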