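#' Layer descriptors for architecture specs
#'
#' Small constructors for the declarative layer list of an
#' [ArchitectureSpec-class]. Convolutions are valid (unpadded) with stride 1;
#' max-pooling uses `floor((len - size) / stride) + 1` output positions.
#'
#' @param filters,width,stride convolution filter count, width (nt) and
#'   stride (only stride 1 is supported).
#' @param size pooling window size; `stride` defaults to `size`.
#' @param rate dropout rate in `[0, 1)`.
#' @param units dense / output layer width.
#' @param activation output head activation, `"sigmoid"` or `"linear"`.
#' @return A named list describing the layer.
#' @name layer-spec
NULL

#' @rdname layer-spec
#' @export
convLayer <- function(filters, width, stride = 1L) {
  if (stride != 1L) stop("only stride-1 convolutions are supported")
  list(kind = "conv1d", filters = as.integer(filters),
       width = as.integer(width), stride = 1L)
}

#' @rdname layer-spec
#' @export
batchNormLayer <- function() list(kind = "batchnorm")

#' @rdname layer-spec
#' @export
reluLayer <- function() list(kind = "relu")

#' @rdname layer-spec
#' @export
maxPoolLayer <- function(size, stride = size) {
  list(kind = "maxpool", size = as.integer(size), stride = as.integer(stride))
}

#' @rdname layer-spec
#' @export
dropoutLayer <- function(rate) {
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)")
  list(kind = "dropout", rate = as.numeric(rate))
}

#' @rdname layer-spec
#' @export
flattenLayer <- function() list(kind = "flatten")

#' @rdname layer-spec
#' @export
denseLayer <- function(units) list(kind = "dense", units = as.integer(units))

#' @rdname layer-spec
#' @export
outputLayer <- function(units, activation = c("sigmoid", "linear")) {
  activation <- match.arg(activation)
  list(kind = "output", units = as.integer(units), activation = activation)
}

#' Assemble an architecture spec
#'
#' @param name model family name.
#' @param inputLength input sequence length in nt.
#' @param layers ordered list of layer descriptors; must end with
#'   [outputLayer()].
#' @return An [ArchitectureSpec-class].
#' @export
architectureSpec <- function(name, inputLength, layers) {
  out <- layers[[length(layers)]]
  new("ArchitectureSpec", name = name,
      inputLength = as.integer(inputLength),
      nTasks = out$units,
      headActivation = out$activation,
      layers = layers)
}

#' Basset-style architecture
#'
#' Multi-task chromatin accessibility classifier: three conv blocks
#' (300x19, 200x11, 200x7 filters with batch norm, ReLU, and pooling 3/4/2)
#' followed by two 1000-unit dense blocks with dropout 0.3 and a sigmoid
#' output head.
#'
#' @param inputLength input length in nt (600 natively; use 630 when
#'   training with 30-nt insertion padding).
#' @param nTasks number of output tasks (161 cell types natively).
#' @return An [ArchitectureSpec-class].
#' @export
bassetSpec <- function(inputLength = 600L, nTasks = 161L) {
  architectureSpec("basset", inputLength, list(
    convLayer(300, 19), batchNormLayer(), reluLayer(), maxPoolLayer(3),
    convLayer(200, 11), batchNormLayer(), reluLayer(), maxPoolLayer(4),
    convLayer(200, 7), batchNormLayer(), reluLayer(), maxPoolLayer(2),
    flattenLayer(),
    denseLayer(1000), batchNormLayer(), reluLayer(), dropoutLayer(0.3),
    denseLayer(1000), batchNormLayer(), reluLayer(), dropoutLayer(0.3),
    outputLayer(nTasks, "sigmoid")))
}

#' DeepSTARR-style architecture
#'
#' Two-task enhancer activity regressor: four conv blocks (256x7, 60x3,
#' 60x5, 120x3, each with batch norm, ReLU, pool 2), two 256-unit dense
#' blocks with dropout 0.4, and a linear output head.
#'
#' @param inputLength input length in nt (249 natively).
#' @param nTasks number of regression tasks (2 natively: developmental and
#'   housekeeping promoters).
#' @return An [ArchitectureSpec-class].
#' @export
deepstarrSpec <- function(inputLength = 249L, nTasks = 2L) {
  architectureSpec("deepstarr", inputLength, list(
    convLayer(256, 7), batchNormLayer(), reluLayer(), maxPoolLayer(2),
    convLayer(60, 3), batchNormLayer(), reluLayer(), maxPoolLayer(2),
    convLayer(60, 5), batchNormLayer(), reluLayer(), maxPoolLayer(2),
    convLayer(120, 3), batchNormLayer(), reluLayer(), maxPoolLayer(2),
    flattenLayer(),
    denseLayer(256), batchNormLayer(), reluLayer(), dropoutLayer(0.4),
    denseLayer(256), batchNormLayer(), reluLayer(), dropoutLayer(0.4),
    outputLayer(nTasks, "linear")))
}

#' ChIP-seq-style architecture
#'
#' Single-task TF binding classifier: three conv blocks (64x7, 96x5, 128x5
#' with batch norm, ReLU, dropout 0.2 and pooling 4/4/2), one 256-unit
#' dense block with dropout 0.5, and a single-unit sigmoid head.
#'
#' @param inputLength input length in nt (200 natively).
#' @param nTasks number of output tasks (1 natively).
#' @return An [ArchitectureSpec-class].
#' @export
chipCnnSpec <- function(inputLength = 200L, nTasks = 1L) {
  architectureSpec("chipcnn", inputLength, list(
    convLayer(64, 7), batchNormLayer(), reluLayer(), dropoutLayer(0.2),
    maxPoolLayer(4),
    convLayer(96, 5), batchNormLayer(), reluLayer(), dropoutLayer(0.2),
    maxPoolLayer(4),
    convLayer(128, 5), batchNormLayer(), reluLayer(), dropoutLayer(0.2),
    maxPoolLayer(2),
    flattenLayer(),
    denseLayer(256), batchNormLayer(), reluLayer(), dropoutLayer(0.5),
    outputLayer(nTasks, "sigmoid")))
}

#' Miniature ChIP-style architecture for small-scale experiments
#'
#' A scaled-down motif detector used for fast training on synthetic data
#' and in the test suite: one conv block (batch norm, ReLU) followed by
#' *global* max pooling, a small dense block, and the output head. Global
#' pooling makes the detector translation-invariant, which is what lets a
#' network this small generalize from a few thousand sequences instead of
#' memorizing positions.
#'
#' @param inputLength input length in nt.
#' @param nTasks number of output tasks.
#' @param filters first-layer filter count.
#' @param filterWidth first-layer filter width in nt.
#' @param activation head activation.
#' @return An [ArchitectureSpec-class].
#' @export
miniCnnSpec <- function(inputLength = 200L, nTasks = 1L, filters = 32L,
                        filterWidth = 12L,
                        activation = c("sigmoid", "linear")) {
  activation <- match.arg(activation)
  architectureSpec("mini", inputLength, list(
    convLayer(filters, filterWidth), batchNormLayer(), reluLayer(),
    maxPoolLayer(inputLength - filterWidth + 1L),
    flattenLayer(),
    denseLayer(16), batchNormLayer(), reluLayer(),
    outputLayer(nTasks, activation)))
}

#' Build a trainable model from an architecture spec
#'
#' Performs full shape inference over the layer chain (erroring with the
#' offending layer if a convolution or pooling step would reduce the length
#' to zero) and initializes parameters: He-scaled Gaussian weights for conv
#' and hidden dense layers, Glorot-scaled for the output layer, unit
#' batch-norm scales. Initialization draws from the current RNG stream; pass
#' `seed` for a self-contained reproducible build.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param seed optional integer seed for weight initialization.
#' @return A [SequenceModel-class].
#' @examples
#' m <- buildModel(miniCnnSpec(100), seed = 1)
#' dim(predict(m, randomSequences(3, 100)))
#' @export
buildModel <- function(spec, seed = NULL) {
  methods::validObject(spec)
  doBuild <- function() {
    len <- spec@inputLength
    ch <- 4L
    flat <- NA_integer_  # units once flattened
    layers <- vector("list", length(spec@layers))
    for (i in seq_along(spec@layers)) {
      l <- spec@layers[[i]]
      st <- l
      if (l$kind == "conv1d") {
        if (!is.na(flat)) stop("conv1d after flatten (layer ", i, ")")
        outLen <- len - l$width + 1L
        if (outLen < 1L)
          stop(sprintf("layer %d (conv1d width %d) reduces length %d below 1",
                       i, l$width, len))
        fanIn <- l$width * ch
        st$W <- matrix(stats::rnorm(fanIn * l$filters, 0, sqrt(2 / fanIn)),
                       fanIn, l$filters)
        st$b <- numeric(l$filters)
        len <- outLen; ch <- l$filters
      } else if (l$kind == "batchnorm") {
        nch <- if (is.na(flat)) ch else flat
        st$gamma <- rep(1, nch); st$beta <- numeric(nch)
        st$rmean <- numeric(nch); st$rvar <- rep(1, nch)
      } else if (l$kind == "maxpool") {
        if (!is.na(flat)) stop("maxpool after flatten (layer ", i, ")")
        outLen <- (len - l$size) %/% l$stride + 1L
        if (len < l$size || outLen < 1L)
          stop(sprintf("layer %d (maxpool size %d) reduces length %d below 1",
                       i, l$size, len))
        len <- outLen
      } else if (l$kind == "flatten") {
        flat <- len * ch
      } else if (l$kind %in% c("dense", "output")) {
        if (is.na(flat))
          stop("dense layer ", i, " requires a preceding flatten layer")
        sd <- if (l$kind == "dense") sqrt(2 / flat) else sqrt(1 / flat)
        st$W <- matrix(stats::rnorm(flat * l$units, 0, sd), flat, l$units)
        st$b <- numeric(l$units)
        flat <- l$units
      }
      layers[[i]] <- st
    }
    new("SequenceModel", spec = spec,
        state = list(layers = layers, headActivation = spec@headActivation,
                     inputLength = spec@inputLength, nTasks = spec@nTasks))
  }
  if (is.null(seed)) doBuild() else withSeed(seed, doBuild())
}

#' Number of trainable parameters
#' @param model a [SequenceModel-class].
#' @return Integer count of trainable parameters (conv/dense weights and
#'   biases, batch-norm scales and shifts; running statistics excluded).
#' @export
parameterCount <- function(model) {
  sum(vapply(model@state$layers, function(l) {
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }, numeric(1)))
}

#' Predict task outputs for one-hot sequences
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics,
#' dropout disabled), so predictions are deterministic.
#'
#' @param object a [SequenceModel-class].
#' @param x an L x 4 one-hot matrix, a `(B, L, 4)` array, or a
#'   [LabeledDataset-class].
#' @param batchSize internal batch size.
#' @param ... unused.
#' @return Numeric matrix `(B, nTasks)`; sigmoid heads are bounded in (0, 1).
#' @export
setMethod("predict", "SequenceModel", function(object, x, batchSize = 256L, ...) {
  x <- asSeqArray(x)
  if (dim(x)[2] != object@state$inputLength)
    stop(sprintf("model expects %d nt input, got %d nt",
                 object@state$inputLength, dim(x)[2]))
  n <- dim(x)[1]
  out <- matrix(NA_real_, n, object@state$nTasks)
  for (ix in splitBatches(n, batchSize))
    out[ix, ] <- nnForward(object@state, x[ix, , , drop = FALSE],
                           training = FALSE)$out
  out
})

# Coerce matrix / array / dataset input to a (B, L, 4) array.
asSeqArray <- function(x) {
  if (methods::is(x, "LabeledDataset")) return(x@x)
  if (is.matrix(x)) {
    arr <- array(0, c(1L, nrow(x), ncol(x)))
    arr[1, , ] <- x
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("'x' must be an L x 4 matrix, a (B, L, 4) array, or a LabeledDataset")
}

#' Random one-hot sequences
#'
#' Uniform i.i.d. one-hot DNA, drawn from the current RNG stream.
#'
#' @param n number of sequences.
#' @param length sequence length in nt.
#' @return `(n, length, 4)` array.
#' @export
randomSequences <- function(n, length) randomOneHotArray(n, length)

#' Gradient of one task output with respect to the input
#'
#' Evaluation-mode backward pass returning d(output\[task\]) / d(input) for
#' every sequence in the batch; gradients are taken through the head
#' activation.
#'
#' @param model a [SequenceModel-class].
#' @param x input as accepted by [predict()][predict,SequenceModel-method].
#' @param taskIndex 1-based output task index.
#' @return `(B, L, 4)` array of input gradients.
#' @export
inputGradient <- function(model, x, taskIndex = 1L) {
  x <- asSeqArray(x)
  state <- model@state
  if (taskIndex < 1L || taskIndex > state$nTasks)
    stop("taskIndex out of range")
  fw <- nnForward(state, x, training = FALSE)
  dPost <- matrix(0, dim(x)[1], state$nTasks)
  dPost[, taskIndex] <- 1
  dPre <- headPostToPre(state, fw$caches, dPost)
  nnBackward(state, fw$caches, dPre)$dX
}

#' Serialize an architecture spec to YAML
#'
#' @param spec an [ArchitectureSpec-class].
#' @param path YAML file path.
#' @return `writeArchitectureSpec` returns `path` invisibly;
#'   `readArchitectureSpec` returns the spec.
#' @export
writeArchitectureSpec <- function(spec, path) {
  yaml::write_yaml(list(name = spec@name, input_length = spec@inputLength,
                        layers = spec@layers), path)
  invisible(path)
}

#' @rdname writeArchitectureSpec
#' @export
readArchitectureSpec <- function(path) {
  v <- yaml::read_yaml(path)
  layers <- lapply(v$layers, function(l) {
    for (f in c("filters", "width", "stride", "size", "units"))
      if (!is.null(l[[f]])) l[[f]] <- as.integer(l[[f]])
    l
  })
  architectureSpec(v$name, v$input_length, layers)
}
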