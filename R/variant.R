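#' Build a reference/alternative one-hot sequence pair for a variant
#'
#' Encodes the reference window and substitutes the alternative allele at
#' the variant position, verifying that the window actually carries the
#' stated reference allele. The two matrices differ at exactly one position.
#'
#' @param window reference DNA string of the model's input length, centered
#'   on the element of interest.
#' @param position 0-based offset of the variant within the window.
#' @param ref,alt single-letter reference and alternative alleles
#'   (`ref != alt`).
#' @return List with one-hot matrices `ref` and `alt`.
#' @examples
#' p <- buildVariantPair("ACGTACGT", 3, "T", "C")
#' which(rowSums(p$ref != p$alt) > 0) # position 4 (1-based)
#' @export
buildVariantPair <- function(window, position, ref, alt) {
  window <- toupper(as.character(window))
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% DNA_BASES4 || !alt %in% DNA_BASES4)
    stop("ref and alt must be single A/C/G/T letters")
  if (ref == alt) stop("ref and alt alleles must differ")
  L <- nchar(window)
  if (position < 0 || position >= L)
    stop("variant position lies outside the window")
  i <- as.integer(position) + 1L
  have <- substr(window, i, i)
  if (have != ref)
    stop(sprintf("window has '%s' at 0-based position %d, expected ref '%s'",
                 have, position, ref))
  refX <- oneHotEncode(window)
  altX <- refX
  altX[i, ] <- 0
  altX[i, match(alt, DNA_BASES4)] <- 1
  list(ref = refX, alt = altX)
}

#' Center an element within a fixed-length window
#'
#' Helper for mapping element-relative variant positions into a model-length
#' window extracted around the element: returns the 0-based offset of the
#' element's first base within the window. With an even leftover the element
#' sits exactly centered; with an odd leftover the extra base goes to the 3'
#' side.
#'
#' @param elementLength element length in nt.
#' @param windowLength window (model input) length in nt.
#' @return 0-based offset of the element start within the window.
#' @export
elementWindowOffset <- function(elementLength, windowLength) {
  if (elementLength > windowLength)
    stop("element is longer than the window")
  (windowLength - elementLength) %/% 2L
}

#' Score a variant as a prediction log-ratio
#'
#' Cell-type-agnostic effect size: the model's task outputs are averaged
#' into a single scalar for each of the reference and alternative sequences,
#' and the score is the natural log of their ratio,
#' `log(mean(f(alt)) / mean(f(ref)))`. Swapping the two sequences negates
#' the score exactly. Both mean predictions must be strictly positive
#' (guaranteed for sigmoid heads).
#'
#' @param model a [SequenceModel-class].
#' @param refX,altX one-hot matrices of the model's input length. When the
#'   model was trained with insertion padding, pad both with
#'   [padForInference()] using the *same* seed so the pad content cancels in
#'   the ratio.
#' @param tasks optional integer subset of task outputs to average over
#'   (default: all tasks).
#' @return Numeric effect-size score.
#' @export
scoreVariant <- function(model, refX, altX, tasks = NULL) {
  pr <- predict(model, refX)
  pa <- predict(model, altX)
  if (!is.null(tasks)) {
    pr <- pr[, tasks, drop = FALSE]
    pa <- pa[, tasks, drop = FALSE]
  }
  mr <- mean(pr); ma <- mean(pa)
  if (mr <= 0 || ma <= 0)
    stop("mean predictions must be strictly positive to take the log-ratio")
  log(ma / mr)
}

#' Score a table of variants against one reference window
#'
#' @param model a [SequenceModel-class].
#' @param window reference DNA string of the model's input length.
#' @param variants data.frame with columns `position` (0-based within the
#'   window), `ref`, `alt`, and optionally `element_id` and `measured`.
#' @param insertMax 3' pad length for insertion-trained models (pad content
#'   is shared within each ref/alt pair).
#' @param seed seed for the pad content.
#' @return The input data.frame with a `predicted` column appended.
#' @export
scoreVariantTable <- function(model, window, variants, insertMax = 0L,
                              seed = 1L) {
  stopifnot(is.data.frame(variants),
            all(c("position", "ref", "alt") %in% names(variants)))
  preds <- vapply(seq_len(nrow(variants)), function(i) {
    pair <- buildVariantPair(window, variants$position[i],
                             variants$ref[i], variants$alt[i])
    if (insertMax > 0L) {
      ps <- mixSeed(seed, i)
      pair$ref <- padForInference(pair$ref, insertMax, seed = ps)
      pair$alt <- padForInference(pair$alt, insertMax, seed = ps)
    }
    scoreVariant(model, pair$ref, pair$alt)
  }, numeric(1))
  variants$predicted <- preds
  variants
}

#' Evaluate predicted effect sizes against measurements, per experiment
#'
#' Computes the Pearson correlation between measured and predicted effect
#' sizes within each experiment (element), and summarizes performance as
#' the unweighted mean of the per-experiment correlations. Elements with
#' fewer than two variants or zero variance on either axis are excluded
#' from the mean with a warning.
#'
#' @param scores data.frame with columns `element_id`, `measured`,
#'   `predicted`.
#' @return List with `perElement` (data.frame: `element_id`, `n`, `r`) and
#'   `meanR` (mean Pearson r over usable elements).
#' @export
evaluateExperiments <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("element_id", "measured", "predicted") %in% names(scores)))
  ids <- unique(scores$element_id)
  res <- data.frame(element_id = ids, n = NA_integer_, r = NA_real_)
  for (k in seq_along(ids)) {
    g <- scores[scores$element_id == ids[k], ]
    res$n[k] <- nrow(g)
    if (nrow(g) >= 2 && stats::sd(g$measured) > 0 && stats::sd(g$predicted) > 0)
      res$r[k] <- stats::cor(g$measured, g$predicted)
  }
  if (anyNA(res$r))
    warning(sprintf("%d element(s) excluded from the mean (too few variants or zero variance)",
                    sum(is.na(res$r))))
  list(perElement = res, meanR = mean(res$r, na.rm = TRUE))
}

#' Read a variant table from TSV
#'
#' Expects tab-separated columns `element_id`, `position` (0-based within
#' the element window), `ref`, `alt`, `measured`.
#'
#' @param path TSV file path.
#' @return data.frame of variants.
#' @export
readVariantTable <- function(path) {
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("element_id", "position", "ref", "alt", "measured")
  if (!all(need %in% names(v)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  v
}
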