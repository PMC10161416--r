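#' One-hot encode a DNA sequence
#'
#' Encodes an N-free DNA string as an L x 4 matrix with columns in the fixed
#' alphabet order (A, C, G, T); row i carries a single 1 at the column of the
#' i-th base. Input case is normalized to upper case. Sequences containing N
#' are rejected: ambiguous bases are handled upstream by [filterN()], never
#' by soft encoding.
#'
#' @param s a character string or [Biostrings::DNAString] over A/C/G/T.
#' @return L x 4 numeric matrix with `colnames` `c("A","C","G","T")`.
#' @examples
#' oneHotEncode("ACGT")
#' @seealso [oneHotDecode()], [filterN()]
#' @export
oneHotEncode <- function(s) {
  s <- toupper(as.character(s))
  if (length(s) != 1L || nchar(s) == 0L)
    stop("'s' must be a single non-empty DNA string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, DNA_BASES4)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("sequence contains non-ACGT character(s): %s%s",
                 paste(bad, collapse = ", "),
                 if ("N" %in% bad)
                   " (filter N-containing sequences before encoding)" else ""))
  }
  m <- matrix(0, nrow = length(idx), ncol = 4L,
              dimnames = list(NULL, DNA_BASES4))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a strictly one-hot matrix back to a DNA string
#'
#' Inverse of [oneHotEncode()]. Rows that are not exactly one-hot (one 1 and
#' three 0s) are an error: augmented matrices carrying Gaussian noise have no
#' discrete decoding.
#'
#' @param x L x 4 numeric matrix.
#' @return Character string of length L.
#' @examples
#' oneHotDecode(oneHotEncode("GATTACA"))
#' @export
oneHotDecode <- function(x) {
  if (!isStrictOneHot(x))
    stop("matrix is not strictly one-hot; cannot decode")
  paste(DNA_BASES4[max.col(x, ties.method = "first")], collapse = "")
}

#' Test whether a matrix is strictly one-hot
#'
#' @param x numeric matrix.
#' @return `TRUE` if `x` is L x 4 with every entry 0 or 1 and every row
#'   summing to exactly 1.
#' @export
isStrictOneHot <- function(x) {
  is.matrix(x) && ncol(x) == 4L && nrow(x) >= 1L &&
    all(x == 0 | x == 1) && all(rowSums(x) == 1)
}

#' Reverse complement of a one-hot matrix
#'
#' Reverses the position axis and swaps complementary channels
#' (A <-> T, C <-> G), i.e. flips the matrix along both axes under the
#' (A, C, G, T) column order. Works on arbitrary real-valued L x 4 matrices
#' (e.g. attribution maps), not only strict one-hot content.
#'
#' @param x L x 4 numeric matrix.
#' @return L x 4 numeric matrix, the reverse complement.
#' @examples
#' oneHotDecode(reverseComplementOneHot(oneHotEncode("AACG"))) # "CGTT"
#' @export
reverseComplementOneHot <- function(x) {
  if (!is.matrix(x) || ncol(x) != 4L)
    stop("'x' must be an L x 4 matrix")
  out <- x[rev(seq_len(nrow(x))), 4:1, drop = FALSE]
  dimnames(out) <- if (is.null(colnames(x))) NULL else list(NULL, colnames(x))
  out
}
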