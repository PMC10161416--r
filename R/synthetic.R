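#' Generate a synthetic motif-embedded sequence dataset
#'
#' Builds a seed-deterministic labeled dataset that emulates a single-task
#' binary peak-classification problem: every record is uniform-random
#' background DNA; positive records additionally carry planted instances of
#' the supplied motifs. Each motif instance is the consensus with independent
#' per-position substitution at rate `subRate` (a substituted position gets a
#' uniform random *different* base), placed at a uniform random offset.
#' Ground-truth placements are retained in the dataset's `motifMeta` table so
#' that recovery analyses (filter PFMs, attributions) can be scored exactly.
#'
#' Half of the records (rounded up) are positive. Labels are 1 for positives
#' and 0 for negatives even when `embedProb < 1`, i.e. label noise grows as
#' `embedProb` shrinks — deliberately, since `embedProb` models the fraction
#' of "positive" genomic windows that truly contain the driving motif.
#'
#' @param nRecords number of records.
#' @param length sequence length L in nt.
#' @param motifs list of motifs, each `list(consensus = <string>,
#'   subRate = <rate>)`; a plain character vector is accepted (rate 0).
#' @param embedProb probability that a positive record carries each motif.
#' @param seed integer seed; the dataset is a pure function of the arguments.
#' @return A [LabeledDataset-class] (all records initially in the train
#'   split; use [splitDataset()] to partition). `motifMeta` holds one row
#'   per planted instance with 1-based `start` positions.
#' @examples
#' ds <- syntheticDataset(20, 100, list(list(consensus = "TGACTCA", subRate = 0.05)))
#' ds
#' @export
syntheticDataset <- function(nRecords, length,
                             motifs = list(list(consensus = "TGACTCA",
                                                subRate = 0.05)),
                             embedProb = 1, seed = 1L) {
  if (embedProb < 0 || embedProb > 1) stop("embedProb must be in [0, 1]")
  if (is.character(motifs))
    motifs <- lapply(motifs, function(m) list(consensus = m, subRate = 0))
  for (m in motifs) {
    if (nchar(m$consensus) >= length)
      stop("motif consensus must be shorter than the sequence length")
    if (grepl("[^ACGT]", toupper(m$consensus)))
      stop("motif consensus must be over A/C/G/T")
  }
  L <- as.integer(length)
  n <- as.integer(nRecords)
  nPos <- ceiling(n / 2)
  withSeed(seed, {
    codes <- matrix(sample.int(4L, n * L, replace = TRUE), nrow = n)
    meta <- list()
    for (i in seq_len(nPos)) {
      for (mi in seq_along(motifs)) {
        if (stats::runif(1) >= embedProb) next
        cons <- match(strsplit(toupper(motifs[[mi]]$consensus), "")[[1]],
                      DNA_BASES4)
        w <- base::length(cons)
        inst <- cons
        sub <- stats::runif(w) < motifs[[mi]]$subRate
        if (any(sub)) {
          # substitute to a uniformly chosen different base
          shift <- sample.int(3L, sum(sub), replace = TRUE)
          inst[sub] <- ((inst[sub] - 1L + shift) %% 4L) + 1L
        }
        start <- sampleInt(1L, L - w + 1L)
        codes[i, start + seq_len(w) - 1L] <- inst
        meta[[base::length(meta) + 1L]] <-
          data.frame(record = i, motif = toupper(motifs[[mi]]$consensus),
                     start = start)
      }
    }
    x <- array(0, dim = c(n, L, 4L))
    pos <- arrayInd(seq_len(n * L), c(n, L))
    x[cbind(pos, as.vector(codes))] <- 1
    labels <- matrix(as.numeric(seq_len(n) <= nPos), ncol = 1L)
    motifMeta <- if (base::length(meta)) do.call(rbind, meta) else NULL
    labeledDataset(x, labels, ids = sprintf("synth_%05d", seq_len(n)),
                   taskKind = "binary", motifMeta = motifMeta)
  })
}
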