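# Internal helpers shared across modules.

# Uniform integer on {lo, ..., hi} drawn from the current RNG stream.
# sample(lo:hi, 1) misbehaves when lo == hi and lo > 1, hence this wrapper.
sampleInt <- function(lo, hi) {
  if (hi < lo) stop("empty integer range")
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Deterministically mix a base seed with stream coordinates (epoch, batch,
# record, ...) into a seed in [0, 2^31 - 2]. Works in doubles; all
# intermediates stay far below 2^53.
mixSeed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# n random one-hot rows (uniform over A, C, G, T); 0 rows allowed.
randomOneHotRows <- function(n) {
  m <- matrix(0, nrow = n, ncol = 4L)
  if (n > 0L) m[cbind(seq_len(n), sample.int(4L, n, replace = TRUE))] <- 1
  m
}

# Random one-hot array (n, L, 4) of n independent uniform sequences.
randomOneHotArray <- function(n, L) {
  idx <- sample.int(4L, n * L, replace = TRUE)
  arr <- array(0, dim = c(n, L, 4L))
  pos <- arrayInd(seq_len(n * L), c(n, L))
  arr[cbind(pos, idx)] <- 1
  arr
}
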