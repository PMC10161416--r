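augs <- list(
  mutation = function(x) augmentMutate(x, 0.15),
  translocation = function(x) augmentTranslocate(x, 0, 30),
  insertion = function(x) augmentInsert(x, 0, 20),
  deletion = function(x) augmentDelete(x, 0, 30),
  inversion = function(x) augmentInvert(x, 0, 30),
  reverse_complement = function(x) augmentReverseComplement(x, 0.5)
)

test_that("discrete transforms preserve strict one-hotness and their length contract", {
  set.seed(21)
  x <- oneHotEncode(randomDnaString(120))
  for (nm in names(augs)) {
    y <- augs[[nm]](x)
    expect_true(isStrictOneHot(y), info = nm)
    expLen <- if (nm == "insertion") 140L else 120L
    expect_identical(nrow(y), expLen, info = nm)
  }
})

test_that("each transform at its degenerate setting is the bit-exact identity", {
  set.seed(22)
  x <- oneHotEncode(randomDnaString(80))
  expect_identical(unname(augmentMutate(x, 0))[, ], unname(x))
  expect_identical(augmentTranslocate(x, 0, 0), x)
  expect_identical(augmentInsert(x, 0, 0), x)
  expect_identical(augmentDelete(x, 0, 0), x)
  expect_identical(augmentInvert(x, 0, 0), x)
  expect_identical(augmentReverseComplement(x, 0), x)
  expect_identical(augmentNoise(x, 0, 0), x)
})

test_that("mutation draws round(L * frac / 0.75) positions and resamples uniformly", {
  set.seed(23)
  x <- oneHotEncode(randomDnaString(600))
  y <- augmentMutate(x, 0.15)
  expect_length(attr(y, "mutatedPositions"), 120L)  # round(600*0.15/0.75)
  # change probability at drawn positions is 3/4 (uniform over 4 letters)
  changed <- 0L; total <- 0L
  for (i in 1:100) {
    xi <- oneHotEncode(randomDnaString(300))
    yi <- augmentMutate(xi, 0.2)
    pos <- unique(attr(yi, "mutatedPositions"))
    changed <- changed + sum(rowSums(abs(yi[pos, , drop = FALSE] -
                                           xi[pos, , drop = FALSE])) > 0)
    total <- total + length(pos)
  }
  expect_gt(total, 5000)
  expect_lt(abs(changed / total - 0.75), 0.02)
  expect_warning(augmentMutate(x, 0.9), "capping")
})

test_that("translocation is a circular roll with the documented semantics", {
  x <- oneHotEncode("ACGTAC")
  expect_identical(oneHotDecode(augseq:::rollRows(x, 3)), "TACACG")
  expect_identical(augseq:::rollRows(x, 6), x)   # full roll
  expect_identical(augseq:::rollRows(x, 0), x)
  # roll +s then -s recovers the input for any s
  set.seed(24)
  y <- oneHotEncode(randomDnaString(50))
  for (s in c(1, 7, 49)) {
    expect_identical(augseq:::rollRows(augseq:::rollRows(y, s), -s), y)
  }
  # the stochastic transform always yields some roll of its input
  for (i in 1:10) {
    z <- augmentTranslocate(y, 0, 50)
    rolls <- lapply(0:49, function(s) augseq:::rollRows(y, s))
    expect_true(any(vapply(rolls, identical, logical(1), z)))
  }
})

test_that("insertion places flank padding as floor(p/2) 5' and the remainder 3'", {
  set.seed(25)
  s <- randomDnaString(40)
  x <- oneHotEncode(s)
  # maximal-length insertion leaves no flank padding: original sequence
  # appears intact around one inserted block
  y <- augmentInsert(x, 20, 20)
  d <- oneHotDecode(y)
  found <- any(vapply(0:40, function(at) {
    substr(d, 1, at) == substr(s, 1, at) &&
      substr(d, at + 21, 60) == substr(s, at + 1, 40)
  }, logical(1)))
  expect_true(found)
  # deterministic core: len 5 at position 10 with insertMax 20 gives pads
  # of 7 nt 5' and 8 nt 3' (remainder from the odd leftover goes 3')
  ins <- oneHotEncode("GGGGG")
  y2 <- augseq:::insertWithPad(x, 10L, ins, 20L)
  expect_identical(nrow(y2), 60L)
  d2 <- oneHotDecode(y2)
  expect_identical(substr(d2, 8, 17), substr(s, 1, 10))    # after 7-nt pad
  expect_identical(substr(d2, 18, 22), "GGGGG")            # insertion
  expect_identical(substr(d2, 23, 52), substr(s, 11, 40))  # rest, then 8-nt pad
})

test_that("deletion excises one contiguous block and pads back to length", {
  set.seed(26)
  s <- randomDnaString(60)
  x <- oneHotEncode(s)
  y <- augmentDelete(x, 10, 10)
  expect_identical(nrow(y), 60L)
  # deterministic core: delete 11 nt starting after position 20; pads are
  # 5 nt 5' and 6 nt 3', survivors contiguous in between
  y2 <- augseq:::deleteWithPad(x, 20L, 11L)
  expect_identical(nrow(y2), 60L)
  d2 <- oneHotDecode(y2)
  expect_identical(substr(d2, 6, 54),
                   paste0(substr(s, 1, 20), substr(s, 32, 60)))
})

test_that("inversion reverse-complements a block in place; full length equals RC", {
  set.seed(27)
  x <- oneHotEncode(randomDnaString(30))
  L <- nrow(x)
  yFull <- augmentInvert(x, L, L)
  expect_identical(yFull, reverseComplementOneHot(x))
  # an inverted homopolymer block becomes its complement
  a <- oneHotEncode(strrep("A", 20))
  yA <- augmentInvert(a, 5, 5)
  expect_identical(sum(yA[, 4]), 5)  # five T rows appeared
  expect_identical(sum(yA[, 1]), 15)
  tPos <- which(yA[, 4] == 1)
  expect_identical(tPos, seq(min(tPos), length.out = 5L))  # contiguous
})

test_that("reverse complement triggers with probability rcProb and is an involution", {
  x <- oneHotEncode(randomDnaString(21))  # odd length: never palindromic
  set.seed(28)
  n <- 2000L
  flipped <- sum(vapply(seq_len(n), function(i) {
    !identical(augmentReverseComplement(x, 0.5), x)
  }, logical(1)))
  expect_lt(abs(flipped / n - 0.5), 0.03)
  expect_identical(
    reverseComplementOneHot(reverseComplementOneHot(x)), x)
})

test_that("Gaussian noise has the requested moments and keeps the shape", {
  set.seed(29)
  x <- oneHotEncode(randomDnaString(5000))
  y <- augmentNoise(x, 0, 0.3)
  d <- as.numeric(y - x)
  expect_identical(dim(y), dim(x))
  expect_lt(abs(sd(d) - 0.3), 0.01)
  expect_lt(abs(mean(d)), 0.01)
  expect_error(augmentNoise(x, 0, -1), "noiseStd")
})

test_that("transforms are pure functions of input, settings and seed", {
  x <- oneHotEncode(randomDnaString(90))
  for (nm in names(augs)) {
    a <- withr::with_seed(99, augs[[nm]](x))
    b <- withr::with_seed(99, augs[[nm]](x))
    expect_identical(a, b, info = nm)
  }
})
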