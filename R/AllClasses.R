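#' @import methods
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Canonical augmentation names in application-priority order
#'
#' When several augmentations are applied to one sequence they are always
#' applied in this fixed order, independent of the order in which they were
#' drawn: inversion, deletion, translocation, insertion, reverse_complement,
#' mutation, noise.
#'
#' @return Character vector of the seven augmentation names.
#' @export
augmentationNames <- function() {
  c("inversion", "deletion", "translocation", "insertion",
    "reverse_complement", "mutation", "noise")
}

#' AugmentationSettings: hyperparameters of the seven sequence augmentations
#'
#' Holds every tunable of the augmentation suite. Units are nucleotides for
#' the range parameters, a fraction of sequence length for `mutateFrac`, a
#' probability for `rcProb`, and raw matrix units for the Gaussian noise
#' parameters.
#'
#' @slot mutateFrac fraction of positions mutated to a *different* base on
#'   average (the internal draw count is corrected for silent mutations).
#' @slot shiftMin,shiftMax translocation (circular roll) magnitude range, nt.
#' @slot insertMin,insertMax insertion length range, nt.
#' @slot deleteMin,deleteMax deletion length range, nt.
#' @slot invertMin,invertMax inversion length range, nt.
#' @slot rcProb probability a sequence is replaced by its reverse complement.
#' @slot noiseMean,noiseStd Gaussian noise parameters added elementwise.
#' @export
setClass("AugmentationSettings", representation(
  mutateFrac = "numeric",
  shiftMin = "integer", shiftMax = "integer",
  insertMin = "integer", insertMax = "integer",
  deleteMin = "integer", deleteMax = "integer",
  invertMin = "integer", invertMax = "integer",
  rcProb = "numeric",
  noiseMean = "numeric", noiseStd = "numeric"
))

setValidity("AugmentationSettings", function(object) {
  msgs <- character(0)
  chkRange <- function(lo, hi, nm) {
    if (lo < 0L) msgs <<- c(msgs, sprintf("%s_min must be >= 0", nm))
    if (hi < lo) msgs <<- c(msgs, sprintf("%s_min must be <= %s_max", nm, nm))
  }
  chkRange(object@shiftMin, object@shiftMax, "shift")
  chkRange(object@insertMin, object@insertMax, "insert")
  chkRange(object@deleteMin, object@deleteMax, "delete")
  chkRange(object@invertMin, object@invertMax, "invert")
  if (object@mutateFrac < 0 || object@mutateFrac > 1)
    msgs <- c(msgs, "mutateFrac must be in [0, 1]")
  if (object@rcProb < 0 || object@rcProb > 1)
    msgs <- c(msgs, "rcProb must be in [0, 1]")
  if (object@noiseStd < 0)
    msgs <- c(msgs, "noiseStd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct augmentation settings
#'
#' Defaults are the settings tuned for Basset-style chromatin accessibility
#' models: `mutateFrac = 0.15`, shift/insert/delete ranges 0--30 nt,
#' `rcProb = 0.5`, Gaussian noise sd 0.3. See [deepstarrAugSettings()] for
#' the enhancer-regression / ChIP-seq defaults.
#'
#' @param mutateFrac,shiftMin,shiftMax,insertMin,insertMax,deleteMin,deleteMax,invertMin,invertMax,rcProb,noiseMean,noiseStd see class slots.
#' @return An [AugmentationSettings-class] object.
#' @examples
#' augmentationSettings(mutateFrac = 0.05, insertMax = 20)
#' @export
augmentationSettings <- function(mutateFrac = 0.15,
                                 shiftMin = 0L, shiftMax = 30L,
                                 insertMin = 0L, insertMax = 30L,
                                 deleteMin = 0L, deleteMax = 30L,
                                 invertMin = 0L, invertMax = 30L,
                                 rcProb = 0.5,
                                 noiseMean = 0, noiseStd = 0.3) {
  new("AugmentationSettings",
      mutateFrac = as.numeric(mutateFrac),
      shiftMin = as.integer(shiftMin), shiftMax = as.integer(shiftMax),
      insertMin = as.integer(insertMin), insertMax = as.integer(insertMax),
      deleteMin = as.integer(deleteMin), deleteMax = as.integer(deleteMax),
      invertMin = as.integer(invertMin), invertMax = as.integer(invertMax),
      rcProb = as.numeric(rcProb),
      noiseMean = as.numeric(noiseMean), noiseStd = as.numeric(noiseStd))
}

#' Basset-style augmentation defaults
#' @return An [AugmentationSettings-class] object.
#' @export
bassetAugSettings <- function() augmentationSettings()

#' DeepSTARR/ChIP-seq-style augmentation defaults
#'
#' `mutateFrac = 0.05`, shift and insert ranges 0--20 nt, delete 0--30 nt,
#' `rcProb = 0`, noise sd 0.3.
#' @return An [AugmentationSettings-class] object.
#' @export
deepstarrAugSettings <- function() {
  augmentationSettings(mutateFrac = 0.05, shiftMax = 20L, insertMax = 20L,
                       deleteMax = 30L, invertMax = 20L, rcProb = 0)
}

setMethod("show", "AugmentationSettings", function(object) {
  cat("AugmentationSettings\n")
  cat(sprintf("  mutateFrac: %g   rcProb: %g   noise: N(%g, %g^2)\n",
              object@mutateFrac, object@rcProb,
              object@noiseMean, object@noiseStd))
  cat(sprintf("  shift: [%d, %d]  insert: [%d, %d]  delete: [%d, %d]  invert: [%d, %d] nt\n",
              object@shiftMin, object@shiftMax, object@insertMin,
              object@insertMax, object@deleteMin, object@deleteMax,
              object@invertMin, object@invertMax))
})

#' AugmentationCurriculum: which augmentations to sample, and how many
#'
#' @slot augSet character subset of [augmentationNames()].
#' @slot settings an [AugmentationSettings-class].
#' @slot maxAugs maximum number of augmentations per sequence.
#' @slot mode `"hard"` (always `maxAugs` augmentations) or `"soft"`
#'   (uniform on 1..`maxAugs`).
#' @export
setClass("AugmentationCurriculum", representation(
  augSet = "character",
  settings = "AugmentationSettings",
  maxAugs = "integer",
  mode = "character"
))

setValidity("AugmentationCurriculum", function(object) {
  msgs <- character(0)
  bad <- setdiff(object@augSet, augmentationNames())
  if (length(bad))
    msgs <- c(msgs, paste("unknown augmentation(s):", paste(bad, collapse = ", ")))
  if (anyDuplicated(object@augSet))
    msgs <- c(msgs, "augSet must not contain duplicates")
  if (length(object@augSet) > 0 && object@maxAugs < 1L)
    msgs <- c(msgs, "maxAugs must be >= 1")
  if (object@maxAugs > length(object@augSet))
    msgs <- c(msgs, "maxAugs must not exceed the number of augmentations in augSet")
  if (!object@mode %in% c("hard", "soft"))
    msgs <- c(msgs, "mode must be 'hard' or 'soft'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an augmentation curriculum
#'
#' @param augSet character vector of augmentation names to sample from.
#' @param settings an [AugmentationSettings-class] object.
#' @param maxAugs maximum number of augmentations applied to one sequence.
#' @param mode `"hard"` applies exactly `maxAugs` augmentations to every
#'   sequence; `"soft"` draws the per-sequence count uniformly from
#'   1..`maxAugs`.
#' @return An [AugmentationCurriculum-class] object.
#' @examples
#' augmentationCurriculum(c("mutation", "insertion"), maxAugs = 2, mode = "soft")
#' @export
augmentationCurriculum <- function(augSet,
                                   settings = augmentationSettings(),
                                   maxAugs = 1L,
                                   mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  new("AugmentationCurriculum", augSet = as.character(augSet),
      settings = settings, maxAugs = as.integer(maxAugs), mode = mode)
}

setMethod("show", "AugmentationCurriculum", function(object) {
  cat(sprintf("AugmentationCurriculum (%s mode, up to %d per sequence)\n",
              object@mode, object@maxAugs))
  cat("  augmentations:", paste(object@augSet, collapse = ", "), "\n")
})

#' LabeledDataset: fixed-length one-hot sequences with labels and splits
#'
#' The container used throughout: `n` records of identical length `L`, each
#' an L x 4 one-hot matrix over (A, C, G, T), a numeric label matrix with one
#' row per record and one column per prediction task, and a train/valid/test
#' split assignment.
#'
#' @slot x numeric array `(n, L, 4)` of one-hot sequences.
#' @slot labels numeric matrix `(n, nTasks)`.
#' @slot ids character record identifiers.
#' @slot split factor with levels `train`, `valid`, `test`.
#' @slot taskKind `"binary"` or `"regression"`.
#' @slot motifMeta data.frame of planted ground-truth motif instances for
#'   synthetic datasets (columns `record`, `motif`, `start`), else empty.
#' @export
setClass("LabeledDataset", representation(
  x = "array",
  labels = "matrix",
  ids = "character",
  split = "factor",
  taskKind = "character",
  motifMeta = "data.frame"
))

setValidity("LabeledDataset", function(object) {
  msgs <- character(0)
  d <- dim(object@x)
  if (length(d) != 3L || d[3] != 4L)
    msgs <- c(msgs, "x must be an (n, L, 4) array")
  n <- d[1]
  if (nrow(object@labels) != n)
    msgs <- c(msgs, "labels must have one row per record")
  if (length(object@ids) != n)
    msgs <- c(msgs, "ids must have one entry per record")
  if (length(object@split) != n)
    msgs <- c(msgs, "split must have one entry per record")
  if (!identical(levels(object@split), c("train", "valid", "test")))
    msgs <- c(msgs, "split levels must be train, valid, test")
  if (!object@taskKind %in% c("binary", "regression"))
    msgs <- c(msgs, "taskKind must be 'binary' or 'regression'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a labeled sequence dataset
#'
#' @param x `(n, L, 4)` numeric array of one-hot sequences, or a list of
#'   equal-sized L x 4 matrices.
#' @param labels numeric matrix (n x nTasks) or vector (one task).
#' @param ids optional record identifiers; defaults to `seq_1 ...`.
#' @param split optional character/factor of `train`/`valid`/`test`
#'   assignments; defaults to all-`train`.
#' @param taskKind `"binary"` or `"regression"`.
#' @param motifMeta optional ground-truth motif placement table.
#' @return A [LabeledDataset-class].
#' @export
labeledDataset <- function(x, labels, ids = NULL, split = NULL,
                           taskKind = c("binary", "regression"),
                           motifMeta = NULL) {
  taskKind <- match.arg(taskKind)
  if (is.list(x)) {
    L <- unique(vapply(x, nrow, integer(1)))
    if (length(L) != 1L)
      stop("all sequences in a dataset must have the same length")
    arr <- array(0, dim = c(length(x), L, 4L))
    for (i in seq_along(x)) arr[i, , ] <- x[[i]]
    x <- arr
  }
  n <- dim(x)[1]
  if (is.null(dim(labels))) labels <- matrix(as.numeric(labels), ncol = 1L)
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  if (is.null(split)) split <- rep("train", n)
  split <- factor(as.character(split), levels = c("train", "valid", "test"))
  if (anyNA(split)) stop("split entries must be 'train', 'valid' or 'test'")
  if (is.null(motifMeta))
    motifMeta <- data.frame(record = integer(0), motif = character(0),
                            start = integer(0))
  new("LabeledDataset", x = x, labels = labels, ids = as.character(ids),
      split = split, taskKind = taskKind, motifMeta = motifMeta)
}

setMethod("show", "LabeledDataset", function(object) {
  d <- dim(object@x)
  tab <- table(object@split)
  cat(sprintf("LabeledDataset: %d records x %d nt, %d %s task(s)\n",
              d[1], d[2], ncol(object@labels), object@taskKind))
  cat(sprintf("  split: train %d / valid %d / test %d\n",
              tab[["train"]], tab[["valid"]], tab[["test"]]))
  if (nrow(object@motifMeta))
    cat(sprintf("  planted motif instances: %d\n", nrow(object@motifMeta)))
})

#' @describeIn LabeledDataset-class number of records
#' @param x a `LabeledDataset`
#' @export
setMethod("length", "LabeledDataset", function(x) dim(x@x)[1])

#' Subset a dataset by record index
#' @param x a [LabeledDataset-class]
#' @param i integer or logical index over records
#' @param j,...,drop ignored
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(length(x))[i]
  meta <- x@motifMeta[x@motifMeta$record %in% idx, , drop = FALSE]
  if (nrow(meta)) meta$record <- match(meta$record, idx)
  new("LabeledDataset",
      x = x@x[idx, , , drop = FALSE],
      labels = x@labels[idx, , drop = FALSE],
      ids = x@ids[idx],
      split = x@split[idx],
      taskKind = x@taskKind,
      motifMeta = meta)
})

#' Dataset accessors
#'
#' `seqArray` returns the `(n, L, 4)` one-hot array, `labelMatrix` the label
#' matrix, `recordIds` the identifiers, `datasetSplit` the split factor,
#' `taskKind` the task type, `seqLength` the common sequence length, and
#' `splitSubset` the sub-dataset belonging to one split.
#'
#' @param dataset a [LabeledDataset-class]
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
seqArray <- function(dataset) dataset@x

#' @rdname dataset-accessors
#' @export
labelMatrix <- function(dataset) dataset@labels

#' @rdname dataset-accessors
#' @export
recordIds <- function(dataset) dataset@ids

#' @rdname dataset-accessors
#' @export
datasetSplit <- function(dataset) dataset@split

#' @rdname dataset-accessors
#' @export
taskKind <- function(dataset) dataset@taskKind

#' @rdname dataset-accessors
#' @export
seqLength <- function(dataset) dim(dataset@x)[2]

#' @rdname dataset-accessors
#' @export
motifMeta <- function(dataset) dataset@motifMeta

#' @rdname dataset-accessors
#' @param which one of `"train"`, `"valid"`, `"test"`
#' @export
splitSubset <- function(dataset, which = c("train", "valid", "test")) {
  which <- match.arg(which)
  dataset[dataset@split == which]
}

#' ArchitectureSpec: a declarative layer list for a sequence CNN
#'
#' @slot name model family name.
#' @slot inputLength expected sequence length in nt.
#' @slot nTasks number of output tasks.
#' @slot headActivation `"sigmoid"` or `"linear"`.
#' @slot layers ordered list of layer descriptors (see [convLayer()] and
#'   friends).
#' @export
setClass("ArchitectureSpec", representation(
  name = "character",
  inputLength = "integer",
  nTasks = "integer",
  headActivation = "character",
  layers = "list"
))

setValidity("ArchitectureSpec", function(object) {
  msgs <- character(0)
  kinds <- vapply(object@layers, function(l) l$kind, character(1))
  ok <- c("conv1d", "batchnorm", "relu", "maxpool", "dropout", "dense",
          "flatten", "output")
  if (length(bad <- setdiff(kinds, ok)))
    msgs <- c(msgs, paste("unknown layer kind(s):", paste(bad, collapse = ", ")))
  if (!object@headActivation %in% c("sigmoid", "linear"))
    msgs <- c(msgs, "headActivation must be 'sigmoid' or 'linear'")
  if (length(kinds) == 0L || kinds[length(kinds)] != "output")
    msgs <- c(msgs, "the final layer must be an output layer")
  if (object@inputLength < 1L) msgs <- c(msgs, "inputLength must be >= 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec '%s': input %d nt x 4 -> %d task(s) [%s head]\n",
              object@name, object@inputLength, object@nTasks,
              object@headActivation))
  for (l in object@layers) {
    p <- l[setdiff(names(l), "kind")]
    cat(sprintf("  %-10s %s\n", l$kind,
                paste(sprintf("%s=%s", names(p), unlist(p)), collapse = " ")))
  }
})

#' SequenceModel: a built, trainable sequence-to-function network
#'
#' Created by [buildModel()]. Holds the architecture spec together with the
#' parameter state (weights, biases, batch-norm statistics). Use
#' [predict()][predict,SequenceModel-method] for inference,
#' [pretrainModel()]/[finetuneModel()] for training.
#'
#' @slot spec the [ArchitectureSpec-class] the model was built from.
#' @slot state internal list of per-layer parameter tensors.
#' @export
setClass("SequenceModel", representation(
  spec = "ArchitectureSpec",
  state = "list"
))

setMethod("show", "SequenceModel", function(object) {
  cat(sprintf("SequenceModel '%s' (%s parameters)\n", object@spec@name,
              format(parameterCount(object), big.mark = ",")))
  cat(sprintf("  input %d nt -> %d task(s), %s head\n",
              object@spec@inputLength, object@spec@nTasks,
              object@spec@headActivation))
})

#' PositionFrequencyMatrix: letter counts under an aligned filter
#'
#' Summarizes the subsequences that strongly activate one first-layer
#' convolutional filter. `counts` has one row per filter position and one
#' column per base (A, C, G, T); every row sums to `nSites`.
#'
#' @slot counts W x 4 integer matrix of letter counts.
#' @slot nSites number of contributing subsequences.
#' @slot filterIndex index of the filter in the first conv layer.
#' @export
setClass("PositionFrequencyMatrix", representation(
  counts = "matrix",
  nSites = "integer",
  filterIndex = "integer"
))

setValidity("PositionFrequencyMatrix", function(object) {
  msgs <- character(0)
  if (ncol(object@counts) != 4L)
    msgs <- c(msgs, "counts must have 4 columns (A, C, G, T)")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (object@nSites > 0L && any(rowSums(object@counts) != object@nSites))
    msgs <- c(msgs, "every row of counts must sum to nSites")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat(sprintf("PositionFrequencyMatrix (filter %d): width %d, %d site(s)\n",
              object@filterIndex, nrow(object@counts), object@nSites))
  if (object@nSites > 0L)
    cat("  consensus:", pfmConsensus(object), "\n")
})

#' Position probability matrix of a filter PFM
#' @param pfm a [PositionFrequencyMatrix-class]
#' @return W x 4 matrix of per-position base probabilities (rows sum to 1).
#' @export
pfmProbabilities <- function(pfm) {
  if (pfm@nSites == 0L)
    return(matrix(NA_real_, nrow(pfm@counts), 4L,
                  dimnames = list(NULL, DNA_BASES4)))
  p <- pfm@counts / pfm@nSites
  dimnames(p) <- list(NULL, DNA_BASES4)
  p
}

#' Consensus string of a filter PFM
#'
#' Ties are broken toward the alphabetically first base.
#' @param pfm a [PositionFrequencyMatrix-class]
#' @return Consensus sequence as a character string.
#' @export
pfmConsensus <- function(pfm) {
  if (pfm@nSites == 0L) return("")
  paste(DNA_BASES4[max.col(pfm@counts, ties.method = "first")], collapse = "")
}

#' AttributionMap: per-position, per-base importance scores
#'
#' @slot values L x 4 numeric matrix of attribution scores.
#' @slot sequenceId identifier of the scored sequence.
#' @slot corrected whether the gradient correction (removal of the
#'   per-position uniform component) has been applied; when `TRUE` every
#'   row sums to zero.
#' @export
setClass("AttributionMap", representation(
  values = "matrix",
  sequenceId = "character",
  corrected = "logical"
))

setValidity("AttributionMap", function(object) {
  msgs <- character(0)
  if (ncol(object@values) != 4L)
    msgs <- c(msgs, "values must have 4 columns (A, C, G, T)")
  if (isTRUE(object@corrected) &&
      any(abs(rowSums(object@values)) > 1e-6))
    msgs <- c(msgs, "corrected maps must sum to 0 at every position")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AttributionMap", function(object) {
  cat(sprintf("AttributionMap '%s': %d positions, %s\n", object@sequenceId,
              nrow(object@values),
              if (object@corrected) "gradient-corrected" else "uncorrected"))
})

#' Attribution score matrix
#' @param map an [AttributionMap-class]
#' @return L x 4 numeric matrix (columns A, C, G, T).
#' @export
attributionValues <- function(map) map@values
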