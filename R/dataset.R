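#' Remove sequences containing ambiguous (N) bases
#'
#' Keeps exactly the records whose sequence has no N character, preserving
#' input order. The operation is idempotent. This mirrors the standard
#' cleaning step applied to genomic training sets before one-hot encoding:
#' ambiguous bases are dropped rather than soft-encoded.
#'
#' @param seqs character vector of DNA strings (optionally named) or a
#'   [Biostrings::DNAStringSet].
#' @return Object of the same type containing only N-free sequences.
#' @examples
#' filterN(c(a = "ACGT", b = "ACNT", c = "GGGG"))
#' @export
filterN <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    keep <- Biostrings::vcountPattern("N", seqs, fixed = TRUE) == 0L
    return(seqs[keep])
  }
  s <- toupper(as.character(seqs))
  seqs[!grepl("N", s, fixed = TRUE)]
}

#' Randomly split a dataset into train/valid/test
#'
#' Assigns records to splits by a seed-deterministic uniform permutation.
#' The validation and test splits receive `floor(n * f)` records each; the
#' remainder (including rounding leftovers) goes to the training split, so
#' with `n = 10000` and fractions `(0.7, 0.1, 0.2)` the sizes are exactly
#' `(7000, 1000, 2000)`.
#'
#' @param dataset a [LabeledDataset-class] (existing split assignments are
#'   discarded).
#' @param fractions numeric length-3 vector `(train, valid, test)` summing
#'   to 1 (tolerance 1e-9).
#' @param seed integer seed controlling the permutation.
#' @return The dataset with a fresh split factor.
#' @export
splitDataset <- function(dataset, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0))
    stop("fractions must be 3 non-negative numbers (train, valid, test)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  n <- length(dataset)
  nValid <- floor(n * fractions[2])
  nTest <- floor(n * fractions[3])
  perm <- withSeed(seed, sample.int(n))
  split <- rep("train", n)
  split[perm[seq_len(nValid)]] <- "valid"
  split[perm[nValid + seq_len(nTest)]] <- "test"
  methods::initialize(dataset,
                      split = factor(split, levels = c("train", "valid", "test")))
}

#' Down-sample negatives to match the positive count
#'
#' Samples `length(pos)` negatives uniformly without replacement (seeded),
#' preserving their original relative order, so that a binary classification
#' set is class-balanced. Up-sampling is never performed: fewer negatives
#' than positives is an error.
#'
#' @param pos,neg vectors (or lists) of positive and negative records; only
#'   `neg` is subsampled, `pos` is returned untouched.
#' @param seed integer seed.
#' @return List with elements `pos` and `neg`, where
#'   `length(neg) == length(pos)`.
#' @export
balanceNegatives <- function(pos, neg, seed = 1L) {
  if (length(neg) < length(pos))
    stop("fewer negatives than positives; negatives are never up-sampled")
  keep <- withSeed(seed, sort(sample.int(length(neg), length(pos))))
  list(pos = pos, neg = neg[keep])
}
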