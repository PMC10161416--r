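# Shared fixtures: all built in code at test time.

randomDnaString <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# minimum Hamming distance of `motif` over all alignments within `s`
# (forward strand only)
bestMotifMismatch <- function(s, motif) {
  sm <- strsplit(motif, "")[[1]]
  w <- length(sm)
  best <- w
  for (o in 0:(nchar(s) - w)) {
    sub <- strsplit(substr(s, o + 1, o + w), "")[[1]]
    best <- min(best, sum(sub != sm))
  }
  best
}

# A linear model: flatten -> single linear output, with weights set
# explicitly; f(x) = sum(W * x) + b under the engine's column-major
# flatten (position index fastest within each channel).
linearSeqModel <- function(L, weights, bias = 0, activation = "linear") {
  spec <- architectureSpec("linear", L,
                          list(flattenLayer(), outputLayer(1L, activation)))
  m <- buildModel(spec, seed = 1)
  stopifnot(length(weights) == L * 4)
  m@state$layers[[2]]$W <- matrix(as.numeric(weights), ncol = 1)
  m@state$layers[[2]]$b <- as.numeric(bias)
  m
}

# flatten an L x 4 matrix the same way the engine does
flattenLike <- function(x) as.numeric(x)
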