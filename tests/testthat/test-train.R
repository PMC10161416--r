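makeTrainFixture <- function(n = 300, L = 60, seed = 50) {
  ds <- syntheticDataset(n, L,
                         motifs = list(list(consensus = "TGACTCAG",
                                            subRate = 0.05)),
                         embedProb = 1, seed = seed)
  splitDataset(ds, c(0.7, 0.15, 0.15), seed = seed)
}

test_that("zero-epoch training returns the model unchanged with an empty log", {
  ds <- makeTrainFixture(40)
  m <- buildModel(miniCnnSpec(60, filters = 4, filterWidth = 6), seed = 1)
  cur <- augmentationCurriculum("mutation", maxAugs = 1)
  r <- pretrainModel(m, ds, cur, pretrainConfig(maxEpochs = 0))
  expect_identical(r$model@state$layers, m@state$layers)
  expect_identical(nrow(r$log), 0L)
  r2 <- finetuneModel(m, ds, finetuneConfig(maxEpochs = 0))
  expect_identical(r2$model@state$layers, m@state$layers)
})

test_that("training reduces the validation loss on an easy motif task", {
  ds <- makeTrainFixture()
  m <- buildModel(miniCnnSpec(60, filters = 8, filterWidth = 10), seed = 2)
  cur <- augmentationCurriculum(c("mutation", "translocation"),
                                deepstarrAugSettings(), maxAugs = 1,
                                mode = "soft")
  r <- pretrainModel(m, ds, cur,
                     pretrainConfig(learningRate = 5e-3, maxEpochs = 6,
                                    batchSize = 16, seed = 3))
  expect_lt(min(r$log$valid_loss), r$log$valid_loss[1])
  expect_identical(r$bestValidLoss, min(r$log$valid_loss))
  expect_identical(r$log$lr[1], 5e-3)
})

test_that("the returned checkpoint is the minimum-validation-loss epoch", {
  ds <- makeTrainFixture(150)
  m <- buildModel(miniCnnSpec(60, filters = 4, filterWidth = 8), seed = 4)
  r <- finetuneModel(m, ds, finetuneConfig(learningRate = 5e-3,
                                           maxEpochs = 5, batchSize = 16,
                                           seed = 5))
  # recomputed validation loss of the returned model equals the logged best
  vd <- splitSubset(ds, "valid")
  vl <- augseq:::evalLoss(r$model@state, seqArray(vd), labelMatrix(vd),
                          "binary")
  expect_equal(vl, min(r$log$valid_loss), tolerance = 1e-12)
  expect_identical(r$bestEpoch, which.min(r$log$valid_loss))
  # fine-tuning selection never ends worse than its own best epoch
  expect_lte(vl, r$log$valid_loss[nrow(r$log)])
})

test_that("early stopping halts after the configured patience without improvement", {
  ds <- makeTrainFixture(80)
  m <- buildModel(miniCnnSpec(60, filters = 4, filterWidth = 6), seed = 6)
  # zero learning rate: the validation loss can never strictly improve
  # after the first epoch, so training stops at 1 + patience epochs
  r <- finetuneModel(m, ds, finetuneConfig(learningRate = 0, maxEpochs = 50,
                                           earlyStopPatience = 3,
                                           batchSize = 32, seed = 7))
  expect_identical(nrow(r$log), 4L)
  expect_identical(r$bestEpoch, 1L)
})

test_that("the learning-rate schedule follows the logged validation losses", {
  ds <- makeTrainFixture(200)
  m <- buildModel(miniCnnSpec(60, filters = 8, filterWidth = 10), seed = 8)
  r <- finetuneModel(m, ds, finetuneConfig(learningRate = 1e-3,
                                           maxEpochs = 12, batchSize = 16,
                                           lrDecayFactor = 0.1,
                                           lrDecayPatience = 2,
                                           earlyStopPatience = 6, seed = 9))
  # replay the decay rule from the logged losses: decay by 0.1 after 2
  # consecutive epochs without a new best, counter resets on improvement
  lr <- 1e-3; best <- Inf; wait <- 0
  for (e in seq_len(nrow(r$log))) {
    expect_equal(r$log$lr[e], lr, tolerance = 1e-15)
    if (r$log$valid_loss[e] < best) { best <- r$log$valid_loss[e]; wait <- 0 }
    else { wait <- wait + 1; if (wait >= 2) { lr <- lr * 0.1; wait <- 0 } }
  }
})

test_that("training is reproducible for a fixed seed", {
  ds <- makeTrainFixture(100)
  cur <- augmentationCurriculum(c("mutation", "deletion"),
                                deepstarrAugSettings(), maxAugs = 1)
  run <- function() {
    m <- buildModel(miniCnnSpec(60, filters = 4, filterWidth = 6), seed = 10)
    pretrainModel(m, ds, cur, pretrainConfig(maxEpochs = 2, batchSize = 32,
                                             seed = 11))
  }
  a <- run(); b <- run()
  expect_identical(a$log, b$log)
  expect_identical(a$model@state$layers, b$model@state$layers)
})

test_that("shape mismatches are caught before training starts", {
  ds <- makeTrainFixture(40)
  cur <- augmentationCurriculum(c("insertion", "mutation"),
                                augmentationSettings(insertMax = 20L),
                                maxAugs = 1)
  m <- buildModel(miniCnnSpec(60, filters = 4, filterWidth = 6), seed = 1)
  # insertion-augmented batches are 80 nt but the model expects 60 nt
  expect_error(pretrainModel(m, ds, cur, pretrainConfig(maxEpochs = 1)),
               "80 nt")
})

test_that("finetuning pads inputs for insertion-trained models", {
  ds <- makeTrainFixture(60)
  m <- buildModel(miniCnnSpec(75, filters = 4, filterWidth = 6), seed = 1)
  r <- finetuneModel(m, ds, finetuneConfig(maxEpochs = 1, batchSize = 32),
                     insertMax = 15)
  expect_identical(nrow(r$log), 1L)
  log <- r$log
  p <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingLog(log, p)
  expect_identical(read.delim(p)$epoch, log$epoch)
})
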