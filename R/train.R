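#' Optimizer and schedule configuration
#'
#' `pretrainConfig()` carries the pretraining defaults: Adam with learning
#' rate 1e-3, weight decay (L2) 1e-6, up to 100 epochs, early stopping with
#' patience 10, and learning-rate decay by a factor of 0.1 when the
#' validation loss has not improved for 5 epochs. `finetuneConfig()` carries
#' the fine-tuning defaults: learning rate 1e-4, weight decay 1e-6, 5 epochs
#' (no early stopping or decay within so short a schedule).
#'
#' @param learningRate initial Adam learning rate.
#' @param weightDecay L2 penalty coefficient.
#' @param maxEpochs maximum number of epochs.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (`Inf` disables).
#' @param lrDecayFactor multiplicative learning-rate decay factor.
#' @param lrDecayPatience epochs without improvement before decaying
#'   (`Inf` disables). The early-stop and decay counters are independent.
#' @param batchSize mini-batch size.
#' @param seed integer seed governing shuffling, augmentation draws, and
#'   dropout.
#' @return A list of class `"OptimConfig"`.
#' @export
pretrainConfig <- function(learningRate = 1e-3, weightDecay = 1e-6,
                           maxEpochs = 100L, earlyStopPatience = 10L,
                           lrDecayFactor = 0.1, lrDecayPatience = 5L,
                           batchSize = 128L, seed = 1L) {
  structure(list(stage = "pretrain", learningRate = learningRate,
                 weightDecay = weightDecay, maxEpochs = as.integer(maxEpochs),
                 earlyStopPatience = earlyStopPatience,
                 lrDecayFactor = lrDecayFactor,
                 lrDecayPatience = lrDecayPatience,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "OptimConfig")
}

#' @rdname pretrainConfig
#' @export
finetuneConfig <- function(learningRate = 1e-4, weightDecay = 1e-6,
                           maxEpochs = 5L, earlyStopPatience = Inf,
                           lrDecayFactor = 1, lrDecayPatience = Inf,
                           batchSize = 128L, seed = 1L) {
  cfg <- pretrainConfig(learningRate, weightDecay, maxEpochs,
                        earlyStopPatience, lrDecayFactor, lrDecayPatience,
                        batchSize, seed)
  cfg$stage <- "finetune"
  cfg
}

#' @export
print.OptimConfig <- function(x, ...) {
  cat(sprintf("OptimConfig [%s]: lr %g, weight decay %g, %d epochs, batch %d\n",
              x$stage, x$learningRate, x$weightDecay, x$maxEpochs,
              x$batchSize))
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

TRAINABLE <- c("W", "b", "gamma", "beta")

adamInit <- function(layers) {
  lapply(layers, function(l) {
    st <- list()
    for (p in TRAINABLE)
      if (!is.null(l[[p]])) st[[p]] <- list(m = l[[p]] * 0, v = l[[p]] * 0)
    st
  })
}

adamStep <- function(layers, grads, opt, lr, wd, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) {
      g <- grads[[i]][[p]] + wd * layers[[i]][[p]]
      opt[[i]][[p]]$m <- b1 * opt[[i]][[p]]$m + (1 - b1) * g
      opt[[i]][[p]]$v <- b2 * opt[[i]][[p]]$v + (1 - b2) * g * g
      mhat <- opt[[i]][[p]]$m / (1 - b1^t)
      vhat <- opt[[i]][[p]]$v / (1 - b2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, opt = opt)
}

# ---- training loops --------------------------------------------------------

# Validation inputs are fixed per call: padded once with a seed-derived pad
# when the model was trained with insertion, then reused across epochs.
prepareValid <- function(dataset, insertMax, seed) {
  vd <- splitSubset(dataset, "valid")
  if (length(vd) == 0L) stop("dataset has no validation split")
  x <- seqArray(vd)
  if (insertMax > 0L) x <- padForInference(x, insertMax, seed = mixSeed(seed, 7L))
  list(x = x, y = labelMatrix(vd))
}

runTraining <- function(model, dataset, optim, curriculum = NULL) {
  state <- model@state
  insertMax <- 0L
  if (!is.null(curriculum) && "insertion" %in% curriculum@augSet)
    insertMax <- curriculum@settings@insertMax
  td <- splitSubset(dataset, "train")
  if (length(td) == 0L) stop("dataset has no training split")
  expect <- seqLength(dataset) + insertMax
  if (state$inputLength != expect)
    stop(sprintf("model expects %d nt but training would produce %d nt inputs",
                 state$inputLength, expect))
  kind <- taskKind(dataset)
  trainX <- seqArray(td)
  trainY <- labelMatrix(td)
  valid <- prepareValid(dataset, insertMax, optim$seed)
  n <- dim(trainX)[1]
  opt <- adamInit(state$layers)
  lr <- optim$learningRate
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    valid_loss = numeric(0), lr = numeric(0))
  bestLoss <- Inf
  bestLayers <- state$layers
  bestEpoch <- 0L
  stopWait <- 0L
  decayWait <- 0L
  t <- 0L
  for (epoch in seq_len(optim$maxEpochs)) {
    perm <- withSeed(mixSeed(optim$seed, epoch, 1L), sample.int(n))
    epochLoss <- 0
    for (bi in seq_along(batches <- splitBatches(n, optim$batchSize))) {
      ix <- perm[batches[[bi]]]
      bx <- trainX[ix, , , drop = FALSE]
      bseed <- mixSeed(optim$seed, epoch, 2L, bi)
      if (!is.null(curriculum))
        bx <- augmentBatch(bx, curriculum, seed = bseed)
      by <- trainY[ix, , drop = FALSE]
      step <- withSeed(mixSeed(bseed, 3L), {  # dropout stream
        fw <- nnForward(state, bx, training = TRUE)
        lg <- lossAndGrad(fw$out, by, kind)
        bw <- nnBackward(fw$state, fw$caches, lg$dPre)
        list(loss = lg$loss, state = fw$state, grads = bw$grads)
      })
      state <- step$state  # batch-norm running stats
      t <- t + 1L
      upd <- adamStep(state$layers, step$grads, opt, lr, optim$weightDecay, t)
      state$layers <- upd$layers
      opt <- upd$opt
      epochLoss <- epochLoss + step$loss * length(ix)
    }
    validLoss <- evalLoss(state, valid$x, valid$y, kind)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epochLoss / n,
                                 valid_loss = validLoss, lr = lr))
    if (validLoss < bestLoss) {
      bestLoss <- validLoss
      bestLayers <- state$layers
      bestEpoch <- epoch
      stopWait <- 0L
      decayWait <- 0L
    } else {
      stopWait <- stopWait + 1L
      decayWait <- decayWait + 1L
      if (is.finite(optim$lrDecayPatience) && decayWait >= optim$lrDecayPatience) {
        lr <- lr * optim$lrDecayFactor
        decayWait <- 0L
      }
      if (is.finite(optim$earlyStopPatience) && stopWait >= optim$earlyStopPatience)
        break
    }
  }
  state$layers <- bestLayers
  list(model = methods::initialize(model, state = state), log = log,
       bestEpoch = bestEpoch, bestValidLoss = bestLoss)
}

#' Pretrain a model with online augmentations
#'
#' First stage of the two-stage curriculum: every training mini-batch is
#' augmented online (each sequence independently, labels unchanged), while
#' validation uses unaugmented sequences (3'-padded with random DNA when the
#' insertion augmentation is in play). Optimization is Adam with the
#' schedule in `optim`; the returned model carries the weights of the epoch
#' with the lowest validation loss.
#'
#' @param model a [SequenceModel-class] whose input length equals the
#'   dataset sequence length (plus `insertMax` when insertion is in the
#'   curriculum's augmentation set).
#' @param dataset a [LabeledDataset-class] with train and valid splits.
#' @param curriculum an [AugmentationCurriculum-class].
#' @param optim an optimizer configuration, see [pretrainConfig()].
#' @return List with `model` (best-validation checkpoint), `log` (one row
#'   per epoch: `epoch`, `train_loss`, `valid_loss`, `lr`), `bestEpoch`, and
#'   `bestValidLoss`.
#' @seealso [finetuneModel()], [augmentBatch()]
#' @export
pretrainModel <- function(model, dataset, curriculum,
                          optim = pretrainConfig()) {
  stopifnot(methods::is(model, "SequenceModel"),
            methods::is(dataset, "LabeledDataset"),
            methods::is(curriculum, "AugmentationCurriculum"))
  if (optim$maxEpochs == 0L)
    return(list(model = model, log = data.frame(epoch = integer(0),
                                                train_loss = numeric(0),
                                                valid_loss = numeric(0),
                                                lr = numeric(0)),
                bestEpoch = 0L, bestValidLoss = NA_real_))
  runTraining(model, dataset, optim, curriculum)
}

#' Fine-tune a model on unaugmented data
#'
#' Second stage of the curriculum: continued training on the original
#' (unperturbed) sequences at a reduced learning rate, removing biases the
#' augmentations may have introduced. No augmentation is applied; if the
#' model expects insertion-padded inputs (`insertMax > 0`), sequences are 3'
#' padded with random DNA for both training and validation. Returns the
#' minimum-validation-loss checkpoint.
#'
#' @param model a (typically pretrained) [SequenceModel-class].
#' @param dataset a [LabeledDataset-class] with train and valid splits.
#' @param optim an optimizer configuration, see [finetuneConfig()].
#' @param insertMax 3' inference-pad length the model was trained with
#'   (0 for models trained without insertion).
#' @return As [pretrainModel()].
#' @export
finetuneModel <- function(model, dataset, optim = finetuneConfig(),
                          insertMax = 0L) {
  stopifnot(methods::is(model, "SequenceModel"),
            methods::is(dataset, "LabeledDataset"))
  if (optim$maxEpochs == 0L)
    return(list(model = model, log = data.frame(epoch = integer(0),
                                                train_loss = numeric(0),
                                                valid_loss = numeric(0),
                                                lr = numeric(0)),
                bestEpoch = 0L, bestValidLoss = NA_real_))
  insertMax <- as.integer(insertMax)
  if (insertMax > 0L) {
    # pad the training sequences once, seed-fixed, then train normally
    padded <- padForInference(seqArray(dataset), insertMax,
                              seed = mixSeed(optim$seed, 11L))
    dataset <- labeledDataset(padded, labelMatrix(dataset),
                              ids = recordIds(dataset),
                              split = as.character(datasetSplit(dataset)),
                              taskKind = taskKind(dataset))
  }
  runTraining(model, dataset, optim, curriculum = NULL)
}

#' Write a training log as TSV
#'
#' @param log data.frame as returned in the `log` element of
#'   [pretrainModel()] / [finetuneModel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrainingLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
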