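# File I/O: FASTA via Biostrings, BED interval extraction via rtracklayer,
# dataset serialization, and YAML round-trips for settings.

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
readFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write DNA sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- if (is.null(nm)) paste0("seq_", seq_along(seqs)) else nm
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Extract interval sequences from a reference using a BED file
#'
#' Reads 0-based half-open BED intervals and returns the corresponding
#' subsequences of the reference (plus strand; BED strand is ignored).
#'
#' @param bedPath BED file path.
#' @param fastaPath reference FASTA path; sequence names must match the BED
#'   chromosome column.
#' @return Named character vector of extracted sequences
#'   (`chrom:start-end` names, 0-based half-open coordinates as in the BED).
#' @export
extractBedSequences <- function(bedPath, fastaPath) {
  gr <- rtracklayer::import(bedPath, format = "BED")
  ref <- Biostrings::readDNAStringSet(fastaPath)
  names(ref) <- sub("\\s.*$", "", names(ref))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chrom), names(ref))
  if (length(missing))
    stop("BED chromosome(s) absent from FASTA: ", paste(missing, collapse = ", "))
  starts <- GenomicRanges::start(gr)  # already 1-based after import
  ends <- GenomicRanges::end(gr)
  out <- character(length(gr))
  for (i in seq_along(gr)) {
    out[i] <- toupper(as.character(
      Biostrings::subseq(ref[[chrom[i]]], start = starts[i], end = ends[i])))
  }
  names(out) <- sprintf("%s:%d-%d", chrom, starts - 1L, ends)
  out
}

#' Save / load a labeled dataset
#'
#' Serializes the dataset container (one-hot array, labels, split indices,
#' ground-truth metadata) to a single file using R's native serialization.
#'
#' @param dataset a [LabeledDataset-class].
#' @param path file path.
#' @return `saveDataset` returns `path` invisibly; `loadDataset` returns the
#'   dataset.
#' @export
saveDataset <- function(dataset, path) {
  stopifnot(methods::is(dataset, "LabeledDataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  dataset <- readRDS(path)
  stopifnot(methods::is(dataset, "LabeledDataset"))
  methods::validObject(dataset)
  dataset
}

#' Write / read augmentation settings as YAML
#'
#' @param settings an [AugmentationSettings-class].
#' @param path YAML file path.
#' @return `writeAugSettings` returns `path` invisibly; `readAugSettings`
#'   returns the settings object.
#' @export
writeAugSettings <- function(settings, path) {
  vals <- list(
    mutate_frac = settings@mutateFrac,
    shift_min = settings@shiftMin, shift_max = settings@shiftMax,
    insert_min = settings@insertMin, insert_max = settings@insertMax,
    delete_min = settings@deleteMin, delete_max = settings@deleteMax,
    invert_min = settings@invertMin, invert_max = settings@invertMax,
    rc_prob = settings@rcProb,
    noise_mean = settings@noiseMean, noise_std = settings@noiseStd)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeAugSettings
#' @export
readAugSettings <- function(path) {
  v <- yaml::read_yaml(path)
  augmentationSettings(
    mutateFrac = v$mutate_frac,
    shiftMin = v$shift_min, shiftMax = v$shift_max,
    insertMin = v$insert_min, insertMax = v$insert_max,
    deleteMin = v$delete_min, deleteMax = v$delete_max,
    invertMin = v$invert_min, invertMax = v$invert_max,
    rcProb = v$rc_prob,
    noiseMean = v$noise_mean, noiseStd = v$noise_std)
}
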