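test_that("variant pairs differ at exactly the variant position", {
  set.seed(60)
  w <- randomDnaString(50)
  pos <- 17L
  ref <- substr(w, pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  p <- buildVariantPair(w, pos, ref, alt)
  diffs <- which(rowSums(p$ref != p$alt) > 0)
  expect_identical(diffs, pos + 1L)
  expect_identical(oneHotDecode(p$ref), w)
  expect_error(buildVariantPair(w, pos, ref, ref), "must differ")
  wrongRef <- setdiff(c("A", "C", "G", "T"), c(ref, alt))[1]
  expect_error(buildVariantPair(w, pos, wrongRef, alt), "expected ref")
  expect_error(buildVariantPair(w, 50, "A", "C"), "outside")
})

test_that("element centering puts the odd leftover base on the 3' side", {
  expect_identical(elementWindowOffset(100L, 600L), 250L)
  expect_identical(elementWindowOffset(187L, 600L), 206L)  # 206 5' / 207 3'
  expect_identical(elementWindowOffset(600L, 600L), 0L)
  expect_error(elementWindowOffset(601L, 600L), "longer")
})

test_that("the effect score is the log-ratio of mean predictions", {
  # a crafted model: all-zero weights except the alt allele channel, so
  # f(ref) = sigmoid(b) and f(alt) = sigmoid(b + w) exactly
  L <- 20L
  w <- strrep("A", L)
  pos <- 7L
  weights <- numeric(L * 4)
  logit <- function(p) log(p / (1 - p))
  # flatten order: position fastest within channel; channel G is the 3rd
  weights[2 * L + (pos + 1)] <- logit(0.5) - logit(0.25)
  m <- linearSeqModel(L, weights, bias = logit(0.25), activation = "sigmoid")
  pair <- buildVariantPair(w, pos, "A", "G")
  s <- scoreVariant(m, pair$ref, pair$alt)
  expect_equal(s, log(0.5 / 0.25), tolerance = 1e-12)  # ln 2
  # antisymmetry under allele swap
  expect_equal(scoreVariant(m, pair$alt, pair$ref), -s, tolerance = 1e-12)
  # identical sequences score exactly zero
  expect_identical(scoreVariant(m, pair$ref, pair$ref), 0)
})

test_that("multi-task scores aggregate by the unweighted task mean", {
  set.seed(61)
  m <- buildModel(miniCnnSpec(40, filters = 4, filterWidth = 5, nTasks = 3,
                              activation = "sigmoid"), seed = 3)
  w <- randomDnaString(40)
  pair <- buildVariantPair(w, 10L, substr(w, 11, 11),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(w, 11, 11))[1])
  s <- scoreVariant(m, pair$ref, pair$alt)
  pr <- predict(m, pair$ref); pa <- predict(m, pair$alt)
  expect_equal(s, log(mean(pa) / mean(pr)), tolerance = 1e-12)
  # task-subset option averages over the chosen tasks only
  s13 <- scoreVariant(m, pair$ref, pair$alt, tasks = c(1, 3))
  expect_equal(s13, log(mean(pa[, c(1, 3)]) / mean(pr[, c(1, 3)])),
               tolerance = 1e-12)
})

test_that("per-element Pearson and the unweighted mean follow the closed form", {
  df <- data.frame(
    element_id = rep(c("e1", "e2"), each = 5),
    measured = c(0.1, -0.4, 0.7, 0.2, -0.9, 1, 2, 3, 4, 5),
    predicted = c(0.3, -0.1, 0.9, 0.1, -1.2, -1, -2, -3, -4, -5))
  r <- evaluateExperiments(df)
  # independent covariance-formula oracle for e1
  g <- df[df$element_id == "e1", ]
  num <- sum((g$measured - mean(g$measured)) * (g$predicted - mean(g$predicted)))
  den <- sqrt(sum((g$measured - mean(g$measured))^2) *
                sum((g$predicted - mean(g$predicted))^2))
  expect_equal(r$perElement$r[1], num / den, tolerance = 1e-12)
  expect_equal(r$perElement$r[2], -1, tolerance = 1e-12)
  expect_equal(r$meanR, mean(r$perElement$r), tolerance = 1e-12)
  # perfect prediction gives r = 1 everywhere
  df2 <- data.frame(element_id = rep("e", 4), measured = 1:4, predicted = 1:4)
  expect_equal(evaluateExperiments(df2)$meanR, 1)
})

test_that("zero-variance elements are excluded from the mean with a warning", {
  df <- data.frame(element_id = rep(c("ok", "flat"), each = 3),
                   measured = c(1, 2, 3, 5, 5, 5),
                   predicted = c(1, 2, 3, 1, 2, 3))
  expect_warning(r <- evaluateExperiments(df), "excluded")
  expect_identical(r$meanR, 1)
  expect_true(is.na(r$perElement$r[r$perElement$element_id == "flat"]))
})

test_that("variant tables score end to end with shared pad content per pair", {
  set.seed(62)
  w <- randomDnaString(30)
  vars <- data.frame(element_id = "e1",
                     position = c(4L, 11L),
                     ref = c(substr(w, 5, 5), substr(w, 12, 12)),
                     alt = NA, measured = c(0.5, -0.2))
  vars$alt <- vapply(seq_len(2), function(i)
    setdiff(c("A", "C", "G", "T"), vars$ref[i])[1], character(1))
  m <- buildModel(miniCnnSpec(40, filters = 4, filterWidth = 5), seed = 9)
  out <- scoreVariantTable(m, w, vars, insertMax = 10, seed = 4)
  expect_identical(nrow(out), 2L)
  expect_true(all(is.finite(out$predicted)))
  out2 <- scoreVariantTable(m, w, vars, insertMax = 10, seed = 4)
  expect_identical(out$predicted, out2$predicted)
  # TSV round trip
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(vars, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readVariantTable(p)$position, vars$position)
})
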