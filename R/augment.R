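# The seven evolution-inspired augmentations. Each is a pure function of its
# input, its hyperparameters, and the current RNG stream: seeding the RNG
# (set.seed) before a call makes it fully reproducible.

#' Random single-nucleotide mutation
#'
#' Draws `round(L * mutateFrac / 0.75)` positions uniformly *with
#' replacement* and replaces each drawn position's base with a uniform random
#' base over all four letters. Because resampling uniformly leaves the
#' original base in place with probability 1/4, the draw count is inflated by
#' 1/0.75 so that on average a fraction `mutateFrac` of positions end up
#' carrying a different base. A position drawn more than once is simply
#' resampled again (last draw wins).
#'
#' @param x strictly one-hot L x 4 matrix.
#' @param mutateFrac target fraction of positions mutated to a different
#'   base, in `[0, 1]`.
#' @return L x 4 one-hot matrix with attribute `"mutatedPositions"`: the
#'   vector of drawn positions (with repeats, in draw order).
#' @examples
#' set.seed(1)
#' y <- augmentMutate(oneHotEncode(strrep("A", 100)), 0.15)
#' length(attr(y, "mutatedPositions")) # round(100 * 0.15 / 0.75) = 20
#' @export
augmentMutate <- function(x, mutateFrac) {
  stopifnot(is.matrix(x), ncol(x) == 4L)
  if (mutateFrac < 0 || mutateFrac > 1)
    stop("mutateFrac must be in [0, 1]")
  L <- nrow(x)
  nDraws <- round(L * mutateFrac / 0.75)
  if (nDraws > L) {
    warning("mutateFrac/0.75 exceeds 1; capping the number of draws at L")
    nDraws <- L
  }
  if (nDraws == 0L) {
    attr(x, "mutatedPositions") <- integer(0)
    return(x)
  }
  pos <- sample.int(L, nDraws, replace = TRUE)
  base <- sample.int(4L, nDraws, replace = TRUE)
  keep <- !duplicated(pos, fromLast = TRUE)  # last draw wins at repeats
  x[pos[keep], ] <- 0
  x[cbind(pos[keep], base[keep])] <- 1
  attr(x, "mutatedPositions") <- pos
  x
}

#' Random translocation (circular roll)
#'
#' Picks a break point by drawing a shift magnitude uniformly on
#' `{shiftMin, ..., shiftMax}` and a direction uniformly at random, then
#' rolls the sequence circularly by the signed shift: the segment pushed past
#' the end re-enters at the other end, i.e. the two segments around the break
#' point swap order.
#'
#' @param x L x 4 matrix.
#' @param shiftMin,shiftMax shift magnitude range in nt; `shiftMax <= L`.
#' @return L x 4 matrix, a row permutation of the input.
#' @export
augmentTranslocate <- function(x, shiftMin = 0L, shiftMax = 30L) {
  L <- nrow(x)
  if (shiftMax > L) stop("shiftMax must not exceed the sequence length")
  if (shiftMin > shiftMax) stop("shiftMin must be <= shiftMax")
  mag <- sampleInt(shiftMin, shiftMax)
  s <- sample(c(-1L, 1L), 1L) * mag
  rollRows(x, s)
}

# Circular roll of the rows of x by signed shift s (forward = toward 3').
rollRows <- function(x, s) {
  L <- nrow(x)
  s <- ((s %% L) + L) %% L
  if (s == 0L) return(x)
  x[((seq_len(L) - 1L - s) %% L) + 1L, , drop = FALSE]
}

#' Random insertion with flank padding to a fixed output length
#'
#' Inserts a uniform-random DNA segment of length drawn uniformly on
#' `{insertMin, ..., insertMax}` at a uniform random position (both sequence
#' ends included). To keep the model input length constant at
#' `L + insertMax`, the leftover length `insertMax - len` is added as
#' uniform-random flanks: `floor(leftover/2)` nt on the 5' side and the
#' remainder on the 3' side.
#'
#' @param x strictly one-hot L x 4 matrix.
#' @param insertMin,insertMax insertion length range in nt.
#' @return One-hot matrix of exactly `L + insertMax` rows.
#' @export
augmentInsert <- function(x, insertMin = 0L, insertMax = 30L) {
  if (insertMin > insertMax) stop("insertMin must be <= insertMax")
  len <- sampleInt(insertMin, insertMax)
  at <- sampleInt(0L, nrow(x))  # original rows kept 5' of the insertion
  insertWithPad(x, at, randomOneHotRows(len), insertMax)
}

# Deterministic core of the insertion: place `ins` after `at` original rows
# and pad with random flanks so the output length is L + insertMax
# (floor(leftover/2) nt 5', remainder 3').
insertWithPad <- function(x, at, ins, insertMax) {
  L <- nrow(x)
  leftover <- insertMax - nrow(ins)
  pad5 <- leftover %/% 2L
  out <- rbind(randomOneHotRows(pad5),
               x[seq_len(at), , drop = FALSE],
               ins,
               x[seq_len(L - at) + at, , drop = FALSE],
               randomOneHotRows(leftover - pad5))
  dimnames(out) <- if (is.null(colnames(x))) NULL else list(NULL, colnames(x))
  out
}

#' Random deletion with flank padding back to the original length
#'
#' Removes a contiguous segment of length drawn uniformly on
#' `{deleteMin, ..., deleteMax}` starting at a uniform random position among
#' those that can contain it; the two flanks are concatenated, and
#' uniform-random DNA pads (`floor(len/2)` nt 5', remainder 3') restore the
#' original length.
#'
#' @param x strictly one-hot L x 4 matrix.
#' @param deleteMin,deleteMax deletion length range in nt; `deleteMax < L`.
#' @return One-hot matrix of exactly L rows.
#' @export
augmentDelete <- function(x, deleteMin = 0L, deleteMax = 30L) {
  L <- nrow(x)
  if (deleteMax >= L) stop("deleteMax must be smaller than the sequence length")
  if (deleteMin > deleteMax) stop("deleteMin must be <= deleteMax")
  len <- sampleInt(deleteMin, deleteMax)
  if (len == 0L) return(x)
  deleteWithPad(x, sampleInt(0L, L - len), len)
}

# Deterministic core of the deletion: excise rows start+1 ... start+len and
# pad with random flanks (floor(len/2) nt 5', remainder 3').
deleteWithPad <- function(x, start, len) {
  keep <- x[-(start + seq_len(len)), , drop = FALSE]
  pad5 <- len %/% 2L
  out <- rbind(randomOneHotRows(pad5), keep, randomOneHotRows(len - pad5))
  dimnames(out) <- if (is.null(colnames(x))) NULL else list(NULL, colnames(x))
  out
}

#' Random inversion (in-place reverse complement of a subsequence)
#'
#' Replaces a contiguous block of length drawn uniformly on
#' `{invertMin, ..., invertMax}`, starting at a uniform random valid
#' position, by its reverse complement; the rest of the sequence is
#' untouched. With `invertMin = invertMax = L` this is exactly the full
#' reverse-complement transformation.
#'
#' @param x L x 4 matrix.
#' @param invertMin,invertMax inversion length range in nt; `invertMax <= L`.
#' @return L x 4 matrix.
#' @export
augmentInvert <- function(x, invertMin = 0L, invertMax = 30L) {
  L <- nrow(x)
  if (invertMax > L) stop("invertMax must not exceed the sequence length")
  if (invertMin > invertMax) stop("invertMin must be <= invertMax")
  len <- sampleInt(invertMin, invertMax)
  if (len == 0L) return(x)
  start <- sampleInt(0L, L - len)
  rows <- start + seq_len(len)
  x[rows, ] <- x[rev(rows), 4:1]
  x
}

#' Stochastic full reverse complement
#'
#' With probability `rcProb` returns the reverse complement of the whole
#' sequence; otherwise returns the input unchanged.
#'
#' @param x L x 4 matrix.
#' @param rcProb probability of applying the reverse complement.
#' @return L x 4 matrix.
#' @export
augmentReverseComplement <- function(x, rcProb = 0.5) {
  if (rcProb < 0 || rcProb > 1) stop("rcProb must be in [0, 1]")
  if (stats::runif(1) < rcProb) reverseComplementOneHot(x) else x
}

#' Additive Gaussian noise
#'
#' Adds an independent draw from `N(noiseMean, noiseStd^2)` to every element
#' of the matrix. The output is real-valued and no longer one-hot; it is
#' intended for model input only, not for decoding.
#'
#' @param x L x 4 numeric matrix.
#' @param noiseMean,noiseStd Gaussian parameters; `noiseStd >= 0`.
#' @return L x 4 numeric matrix.
#' @export
augmentNoise <- function(x, noiseMean = 0, noiseStd = 0.3) {
  if (noiseStd < 0) stop("noiseStd must be >= 0")
  x + matrix(stats::rnorm(length(x), noiseMean, noiseStd),
             nrow = nrow(x), ncol = ncol(x))
}

#' Apply one named augmentation under a settings object
#'
#' Dispatch helper used by the batch scheduler; draws all randomness from the
#' current RNG stream.
#'
#' @param x L x 4 matrix.
#' @param name one of [augmentationNames()].
#' @param settings an [AugmentationSettings-class].
#' @return Transformed matrix (length L + insertMax for `"insertion"`,
#'   length L otherwise).
#' @export
applyAugmentation <- function(x, name, settings) {
  switch(name,
    inversion = augmentInvert(x, settings@invertMin, settings@invertMax),
    deletion = augmentDelete(x, settings@deleteMin, settings@deleteMax),
    translocation = augmentTranslocate(x, settings@shiftMin, settings@shiftMax),
    insertion = augmentInsert(x, settings@insertMin, settings@insertMax),
    reverse_complement = augmentReverseComplement(x, settings@rcProb),
    mutation = augmentMutate(x, settings@mutateFrac),
    noise = augmentNoise(x, settings@noiseMean, settings@noiseStd),
    stop(sprintf("unknown augmentation '%s'", name))
  )
}
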