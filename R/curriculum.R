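#' Draw the augmentation subset for one sequence
#'
#' In `"hard"` mode the subset size is always `maxAugs`; in `"soft"` mode it
#' is uniform on `{1, ..., maxAugs}`. The subset is sampled without
#' replacement from the curriculum's augmentation set and returned in the
#' fixed application-priority order ([augmentationNames()]), regardless of
#' draw order.
#'
#' @param curriculum an [AugmentationCurriculum-class].
#' @return Character vector of augmentation names, priority-ordered.
#' @export
sampleAugmentationSubset <- function(curriculum) {
  methods::validObject(curriculum)
  k <- if (curriculum@mode == "hard") curriculum@maxAugs
       else sampleInt(1L, curriculum@maxAugs)
  drawn <- curriculum@augSet[sample.int(length(curriculum@augSet), k)]
  drawn[order(match(drawn, augmentationNames()))]
}

#' Augment a batch of sequences online
#'
#' Applies an independently drawn, priority-ordered augmentation subset to
#' every sequence of the batch; labels are untouched (each augmented
#' sequence keeps the wild-type labels, handled by the caller since only
#' sequences enter here). When `"insertion"` is in the curriculum's
#' augmentation set, every output sequence has length `L + insertMax`:
#' sequences whose drawn subset did not include the insertion are padded at
#' the 3' end with uniform-random DNA of length `insertMax`, so the model
#' always sees a constant input length. Otherwise the length stays L.
#'
#' @param x `(B, L, 4)` array or list of equal-length L x 4 matrices.
#' @param curriculum an [AugmentationCurriculum-class].
#' @param seed optional integer; when given, sequence `i` is augmented under
#'   the derived seed `mixSeed(seed, i)` so batches are reproducible
#'   independent of processing order.
#' @return `(B, L', 4)` array of augmented sequences.
#' @export
augmentBatch <- function(x, curriculum, seed = NULL) {
  if (is.list(x)) {
    Ls <- vapply(x, nrow, integer(1))
    if (length(unique(Ls)) > 1L)
      stop("all sequences in a batch must have the same length")
    recs <- x
  } else {
    x <- asSeqArray(x)
    recs <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  }
  s <- curriculum@settings
  withIns <- "insertion" %in% curriculum@augSet
  outLen <- nrow(recs[[1]]) + if (withIns) s@insertMax else 0L
  augmentOne <- function(m) {
    subset <- sampleAugmentationSubset(curriculum)
    for (nm in subset) m <- applyAugmentation(m, nm, s)
    if (withIns && !("insertion" %in% subset))
      m <- rbind(m, randomOneHotRows(s@insertMax))
    m
  }
  out <- array(0, c(length(recs), outLen, 4L))
  for (i in seq_along(recs)) {
    m <- if (is.null(seed)) augmentOne(recs[[i]])
         else withSeed(mixSeed(seed, i), augmentOne(recs[[i]]))
    out[i, , ] <- m
  }
  out
}

#' Pad sequences for inference after insertion-augmented training
#'
#' Models trained with the insertion augmentation expect inputs of length
#' `L + insertMax`. At evaluation time no augmentation is applied; instead
#' each sequence is padded at the 3' end with a stretch of uniform-random
#' DNA of length `insertMax`, leaving the first L positions untouched.
#'
#' @param x an L x 4 matrix or `(B, L, 4)` array.
#' @param insertMax pad length in nt (0 returns the input unchanged).
#' @param seed optional integer seed for the pad content.
#' @return Object of the input kind with `insertMax` extra 3' positions.
#' @export
padForInference <- function(x, insertMax, seed = NULL) {
  insertMax <- as.integer(insertMax)
  if (insertMax == 0L) return(x)
  padIt <- function() {
    if (is.matrix(x)) {
      rbind(x, randomOneHotRows(insertMax))
    } else {
      x <- asSeqArray(x)
      d <- dim(x)
      out <- array(0, c(d[1], d[2] + insertMax, 4L))
      out[, seq_len(d[2]), ] <- x
      out[, d[2] + seq_len(insertMax), ] <- randomOneHotArray(d[1], insertMax)
      out
    }
  }
  if (is.null(seed)) padIt() else withSeed(seed, padIt())
}
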