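#' Activation-based first-layer filter PFMs
#'
#' For each first-layer convolutional filter, scans its activation (the
#' linear convolution output, before batch norm) across every valid position
#' of the supplied sequences, collects the filter-width subsequences whose
#' activation strictly exceeds `thresholdFrac` times that filter's maximum
#' activation over the whole scan, and stacks them into per-position letter
#' counts. Filters that never activate above threshold (e.g. maximum
#' activation <= 0) are returned with `nSites = 0`.
#'
#' @param model a [SequenceModel-class] whose first parametric layer is a
#'   convolution.
#' @param sequences strictly one-hot sequences: `(B, L, 4)` array, list of
#'   L x 4 matrices, or a [LabeledDataset-class]. A few hundred test-split
#'   sequences are typically plenty.
#' @param thresholdFrac activation threshold as a fraction of the
#'   per-filter maximum, in (0, 1); default 0.5 per the activation-alignment
#'   convention.
#' @param batchSize internal scan batch size.
#' @return List of [PositionFrequencyMatrix-class], one per filter.
#' @export
extractFilterPFMs <- function(model, sequences, thresholdFrac = 0.5,
                              batchSize = 128L) {
  if (thresholdFrac <= 0 || thresholdFrac >= 1)
    stop("thresholdFrac must be in (0, 1)")
  x <- if (is.list(sequences) && !methods::is(sequences, "LabeledDataset"))
    asSeqArray(labeledDataset(sequences, numeric(length(sequences)))@x)
  else asSeqArray(sequences)
  conv <- NULL
  for (l in model@state$layers) if (l$kind == "conv1d") { conv <- l; break }
  if (is.null(conv)) stop("model has no convolutional layer")
  W <- conv$width
  Fn <- ncol(conv$W)
  if (dim(x)[2] < W) stop("sequences are shorter than the filter width")
  n <- dim(x)[1]
  batches <- splitBatches(n, batchSize)
  # pass 1: per-filter maximum activation over the whole scan
  maxAct <- rep(-Inf, Fn)
  acts <- vector("list", length(batches))
  for (bi in seq_along(batches)) {
    a <- convForward(conv, x[batches[[bi]], , , drop = FALSE])$out
    acts[[bi]] <- a
    maxAct <- pmax(maxAct, apply(a, 3, max))
  }
  # pass 2: collect qualifying W-mers
  counts <- lapply(seq_len(Fn), function(f) matrix(0, W, 4L))
  nSites <- integer(Fn)
  for (bi in seq_along(batches)) {
    a <- acts[[bi]]
    bx <- x[batches[[bi]], , , drop = FALSE]
    for (f in seq_len(Fn)) {
      thr <- thresholdFrac * maxAct[f]
      hits <- which(a[, , f, drop = FALSE] > thr, arr.ind = TRUE)
      if (nrow(hits) == 0L) next
      for (h in seq_len(nrow(hits))) {
        b <- hits[h, 1]; p <- hits[h, 2]
        counts[[f]] <- counts[[f]] + bx[b, p + seq_len(W) - 1L, ]
      }
      nSites[f] <- nSites[f] + nrow(hits)
    }
  }
  lapply(seq_len(Fn), function(f) {
    new("PositionFrequencyMatrix",
        counts = matrix(as.integer(round(counts[[f]])), W, 4L),
        nSites = nSites[f], filterIndex = f)
  })
}

#' Export filter PFMs in MEME minimal motif format
#'
#' Writes a MEME version 4 minimal motif file (ACGT alphabet, both strands,
#' background letter frequencies, one MOTIF block per filter with its
#' letter-probability matrix) suitable for downstream motif comparison with
#' Tomtom. Zero-site filters are skipped with a message. Users matching
#' against the JASPAR vertebrate collection conventionally exclude the
#' low-complexity profiles MA1929.1 and MA0615.1, which otherwise absorb
#' low-information filters.
#'
#' @param pfms list of [PositionFrequencyMatrix-class] (as from
#'   [extractFilterPFMs()]).
#' @param path output file path.
#' @param background length-4 background frequencies for A, C, G, T.
#' @param prefix motif name prefix; motifs are named `<prefix><filterIndex>`.
#' @return `path`, invisibly.
#' @export
writeMeme <- function(pfms, path, background = rep(0.25, 4),
                      prefix = "filter_") {
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %g C %g G %g T %g", background[1], background[2],
                       background[3], background[4]), ""), con)
  skipped <- 0L
  for (pfm in pfms) {
    if (pfm@nSites == 0L) { skipped <- skipped + 1L; next }
    p <- pfmProbabilities(pfm)
    writeLines(sprintf("MOTIF %s%d", prefix, pfm@filterIndex), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(p), pfm@nSites), con)
    writeLines(apply(p, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  if (skipped > 0L)
    message(skipped, " filter(s) with zero qualifying sites were skipped")
  invisible(path)
}

#' Expected-gradient attribution map with random DNA references
#'
#' Estimates per-position, per-base importance of one task output for one
#' sequence by expected gradients: for each of `nReferences` uniform-random
#' one-hot DNA reference sequences, the input is interpolated a uniform
#' random distance toward the reference, the gradient of the task output is
#' taken there, and the contribution `(x - reference) * gradient` is
#' averaged over references (single interpolation sample per reference;
#' `nReferences` controls the estimator variance).
#'
#' @param model a differentiable [SequenceModel-class].
#' @param x strictly one-hot L x 4 matrix at the model's input length.
#' @param taskIndex 1-based output task to attribute.
#' @param nReferences number of random references (default 1000).
#' @param seed optional integer seed for references and interpolation.
#' @param sequenceId identifier stored in the map.
#' @param batchSize internal batch size.
#' @return An uncorrected [AttributionMap-class]; apply
#'   [gradientCorrection()] before logo plotting.
#' @export
attributionMap <- function(model, x, taskIndex = 1L, nReferences = 1000L,
                           seed = NULL, sequenceId = "seq", batchSize = 128L) {
  if (nReferences < 1L) stop("nReferences must be >= 1")
  stopifnot(is.matrix(x), ncol(x) == 4L)
  L <- nrow(x)
  run <- function() {
    acc <- matrix(0, L, 4L)
    done <- 0L
    while (done < nReferences) {
      nb <- min(batchSize, nReferences - done)
      refs <- randomOneHotArray(nb, L)
      alpha <- stats::runif(nb)
      interp <- array(0, c(nb, L, 4L))
      diffs <- array(0, c(nb, L, 4L))
      for (i in seq_len(nb)) {
        d <- x - refs[i, , ]
        diffs[i, , ] <- d
        interp[i, , ] <- refs[i, , ] + alpha[i] * d
      }
      g <- inputGradient(model, interp, taskIndex)
      contrib <- diffs * g
      acc <- acc + apply(contrib, c(2, 3), sum)
      done <- done + nb
    }
    acc / nReferences
  }
  vals <- if (is.null(seed)) run() else withSeed(seed, run())
  dimnames(vals) <- list(NULL, DNA_BASES4)
  new("AttributionMap", values = vals, sequenceId = sequenceId,
      corrected = FALSE)
}

#' Gradient correction of an attribution map
#'
#' Removes, at every position, the component of the attribution that is
#' uniform across the four bases (the per-position mean), so that the four
#' scores at each position sum to zero. The operation is idempotent.
#'
#' @param map an [AttributionMap-class].
#' @return The corrected [AttributionMap-class].
#' @export
gradientCorrection <- function(map) {
  v <- map@values - rowMeans(map@values)
  methods::initialize(map, values = v, corrected = TRUE)
}

#' Write an attribution map as TSV
#'
#' Columns `position` (1-based), `A`, `C`, `G`, `T`; directly consumable by
#' logo-plotting tools.
#'
#' @param map an [AttributionMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAttributionMap <- function(map, path) {
  df <- data.frame(position = seq_len(nrow(map@values)), map@values)
  colnames(df) <- c("position", DNA_BASES4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select high-activity sequences for attribution analysis
#'
#' Returns the indices of the records whose measured label for one task lies
#' in the top `percentile` fraction, the conventional selection for logo
#' figures over enhancer-activity data.
#'
#' @param dataset a [LabeledDataset-class].
#' @param taskIndex 1-based label column.
#' @param percentile top fraction to keep (default 0.01).
#' @return Integer record indices, sorted by decreasing label value.
#' @export
topActivityRecords <- function(dataset, taskIndex = 1L, percentile = 0.01) {
  y <- labelMatrix(dataset)[, taskIndex]
  k <- max(1L, ceiling(length(y) * percentile))
  order(y, decreasing = TRUE)[seq_len(k)]
}
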