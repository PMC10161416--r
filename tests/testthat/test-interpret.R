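# in-test MEME minimal-format parser: the independent oracle for writeMeme
parseMemeFile <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  i <- 1
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF ")) {
      name <- sub("^MOTIF ", "", lines[i])
      hdr <- lines[i + 1]
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
      nsites <- as.integer(sub(".*nsites= *([0-9]+).*", "\\1", hdr))
      mat <- do.call(rbind, lapply(lines[i + 1 + seq_len(w)], function(l)
        as.numeric(strsplit(trimws(l), " +")[[1]])))
      motifs[[name]] <- list(w = w, nsites = nsites, p = mat)
      i <- i + 1 + w
    }
    i <- i + 1
  }
  motifs
}

# model whose single first-layer filter is the one-hot pattern of a k-mer,
# so activation is maximal exactly at matches
kmerDetectorModel <- function(kmer, L) {
  w <- nchar(kmer)
  spec <- architectureSpec("det", L, list(
    convLayer(1L, w), maxPoolLayer(L - w + 1L), flattenLayer(),
    outputLayer(1L, "sigmoid")))
  m <- buildModel(spec, seed = 1)
  m@state$layers[[1]]$W <- matrix(as.numeric(t(oneHotEncode(kmer))), ncol = 1)
  m@state$layers[[1]]$b <- 0
  m
}

test_that("a filter matching a planted k-mer recovers it as the PFM consensus", {
  kmer <- "TGACGTCA"
  set.seed(70)
  seqs <- lapply(1:40, function(i) {
    s <- randomDnaString(60)
    at <- sample(1:52, 1)
    oneHotEncode(paste0(substr(s, 1, at - 1), kmer,
                        substr(s, at + 8, 60)))
  })
  m <- kmerDetectorModel(kmer, 60L)
  pfms <- extractFilterPFMs(m, seqs, thresholdFrac = 0.9)
  expect_length(pfms, 1L)
  expect_identical(pfmConsensus(pfms[[1]]), kmer)
  expect_gte(pfms[[1]]@nSites, 40L)
  # PFM invariants: every row of counts sums to nSites; PPM rows sum to 1
  expect_true(all(rowSums(pfms[[1]]@counts) == pfms[[1]]@nSites))
  expect_equal(rowSums(pfmProbabilities(pfms[[1]])), rep(1, 8))
})

test_that("filter PFM extraction is deterministic and respects the threshold domain", {
  set.seed(71)
  seqs <- randomSequences(20, 40)
  m <- buildModel(miniCnnSpec(40, filters = 6, filterWidth = 7), seed = 2)
  a <- extractFilterPFMs(m, seqs, 0.5)
  b <- extractFilterPFMs(m, seqs, 0.5)
  expect_identical(lapply(a, function(p) p@counts),
                   lapply(b, function(p) p@counts))
  expect_length(a, 6L)
  expect_true(all(vapply(a, function(p) nrow(p@counts), 1L) == 7L))
  expect_error(extractFilterPFMs(m, seqs, 0), "thresholdFrac")
  expect_error(extractFilterPFMs(m, seqs, 1), "thresholdFrac")
})

test_that("MEME export round-trips probabilities and skips empty filters", {
  set.seed(72)
  seqs <- randomSequences(25, 50)
  m <- buildModel(miniCnnSpec(50, filters = 5, filterWidth = 6), seed = 3)
  pfms <- extractFilterPFMs(m, seqs, 0.6)
  # add a synthetic zero-site PFM that must be skipped
  empty <- new("PositionFrequencyMatrix", counts = matrix(0L, 6, 4),
               nSites = 0L, filterIndex = 99L)
  p <- withr::local_tempfile(fileext = ".meme")
  expect_message(writeMeme(c(pfms, empty), p), "skipped")
  lines <- readLines(p)
  expect_identical(lines[1], "MEME version 4")
  expect_true("ALPHABET= ACGT" %in% lines)
  expect_true(any(grepl("^A 0.25 C 0.25 G 0.25 T 0.25$", lines)))
  parsed <- parseMemeFile(p)
  kept <- Filter(function(x) x@nSites > 0, pfms)
  expect_length(parsed, length(kept))
  for (pfm in kept) {
    got <- parsed[[paste0("filter_", pfm@filterIndex)]]
    expect_identical(got$nsites, pfm@nSites)
    expect_lt(max(abs(got$p - pfmProbabilities(pfm))), 1e-4)
  }
})

test_that("attribution of a linear model approaches w * (x - 0.25)", {
  set.seed(73)
  L <- 12L
  weights <- rnorm(L * 4, sd = 0.5)
  m <- linearSeqModel(L, weights, bias = 0, activation = "linear")
  x <- oneHotEncode(randomDnaString(L))
  map <- attributionMap(m, x, nReferences = 4000, seed = 74)
  expected <- matrix(weights, L, 4) * (unname(x) - 0.25)
  expect_false(map@corrected)
  expect_lt(max(abs(attributionValues(map) - expected)), 0.05)
})

test_that("a constant-output model yields an all-zero attribution map", {
  L <- 15L
  m <- linearSeqModel(L, numeric(L * 4), bias = 0.3, activation = "sigmoid")
  x <- oneHotEncode(strrep("ACG", 5))
  map <- attributionMap(m, x, nReferences = 10, seed = 75)
  expect_true(all(attributionValues(map) == 0))
})

test_that("gradient correction centers each position and is idempotent", {
  m <- new("AttributionMap", values = matrix(c(4, 0, 0, 0), 1, 4),
           sequenceId = "hand", corrected = FALSE)
  g <- gradientCorrection(m)
  expect_identical(unname(attributionValues(g)), matrix(c(3, -1, -1, -1), 1, 4))
  expect_true(g@corrected)
  set.seed(76)
  m2 <- new("AttributionMap", values = matrix(rnorm(80), 20, 4),
            sequenceId = "r", corrected = FALSE)
  g2 <- gradientCorrection(m2)
  expect_lt(max(abs(rowSums(attributionValues(g2)))), 1e-12)
  expect_equal(attributionValues(gradientCorrection(g2)),
               attributionValues(g2), tolerance = 1e-15)
  # already-centered input is unchanged
  centered <- m2@values - rowMeans(m2@values)
  g3 <- gradientCorrection(new("AttributionMap", values = centered,
                               sequenceId = "c", corrected = FALSE))
  expect_equal(attributionValues(g3), centered, tolerance = 1e-15)
})

test_that("attribution maps export as logo-ready TSV and select top records", {
  set.seed(77)
  m <- buildModel(miniCnnSpec(30, filters = 4, filterWidth = 5), seed = 5)
  x <- oneHotEncode(randomDnaString(30))
  map <- gradientCorrection(attributionMap(m, x, nReferences = 20, seed = 6))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeAttributionMap(map, p)
  df <- read.delim(p)
  expect_identical(names(df), c("position", "A", "C", "G", "T"))
  expect_equal(as.matrix(df[, 2:5]), attributionValues(map),
               ignore_attr = TRUE)
  ds <- syntheticDataset(50, 30, embedProb = 0, seed = 7)
  top <- topActivityRecords(ds, 1, 0.1)
  expect_length(top, 5L)
  expect_true(all(labelMatrix(ds)[top, 1] >= sort(labelMatrix(ds)[, 1],
                                                  decreasing = TRUE)[5]))
})
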