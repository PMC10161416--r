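# Compact CNN engine: forward/backward passes for the layer kinds used by
# the sequence model zoo (conv1d / batchnorm / relu / maxpool / dropout /
# flatten / dense / output). Convolutions are valid (no padding), stride 1,
# realized as im2col matrix products; pooled length is
# floor((len - size) / stride) + 1. Everything is plain double-precision
# base R; sequence activations are (batch, positions, channels) arrays and
# flat activations are (batch, units) matrices. Internal only.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- im2col convolution ----------------------------------------------------

convForward <- function(ly, A) {
  d <- dim(A); B <- d[1]; Lin <- d[2]; C <- d[3]
  W <- ly$width
  P <- Lin - W + 1L
  X2 <- array(0, c(B, P, W * C))
  for (w in seq_len(W))
    X2[, , ((w - 1L) * C + 1L):(w * C)] <- A[, w:(w + P - 1L), , drop = FALSE]
  X2m <- matrix(X2, B * P, W * C)
  out <- X2m %*% ly$W
  out <- out + rep(ly$b, each = nrow(out))
  list(out = array(out, c(B, P, ncol(ly$W))),
       cache = list(X2m = X2m, B = B, Lin = Lin, C = C, P = P))
}

convBackward <- function(ly, cache, dOut) {
  B <- cache$B; P <- cache$P; C <- cache$C; W <- ly$width
  Fn <- ncol(ly$W)
  dOutm <- matrix(dOut, B * P, Fn)
  dW <- crossprod(cache$X2m, dOutm)
  db <- colSums(dOutm)
  dX2 <- array(tcrossprod(dOutm, ly$W), c(B, P, W * C))
  dA <- array(0, c(B, cache$Lin, C))
  for (w in seq_len(W))
    dA[, w:(w + P - 1L), ] <- dA[, w:(w + P - 1L), , drop = FALSE] +
      dX2[, , ((w - 1L) * C + 1L):(w * C), drop = FALSE]
  list(grads = list(W = dW, b = db), dX = dA)
}

# ---- batch normalization (over samples x positions, per channel) -----------

bnForward <- function(ly, A, training) {
  dims <- dim(A)
  isSeq <- length(dims) == 3L
  Xm <- if (isSeq) matrix(A, dims[1] * dims[2], dims[3]) else A
  N <- nrow(Xm)
  if (training) {
    mu <- colMeans(Xm)
    xc <- Xm - rep(mu, each = N)
    v <- colMeans(xc * xc)
    ly$rmean <- BN_MOMENTUM * ly$rmean + (1 - BN_MOMENTUM) * mu
    ly$rvar <- BN_MOMENTUM * ly$rvar + (1 - BN_MOMENTUM) * v
  } else {
    mu <- ly$rmean
    v <- ly$rvar
    xc <- Xm - rep(mu, each = N)
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(ivar, each = N)
  Y <- xhat * rep(ly$gamma, each = N) + rep(ly$beta, each = N)
  out <- if (isSeq) array(Y, dims) else Y
  list(out = out, layer = ly,
       cache = list(xhat = xhat, ivar = ivar, dims = dims, isSeq = isSeq,
                    training = training))
}

bnBackward <- function(ly, cache, dOut) {
  dims <- cache$dims
  dY <- if (cache$isSeq) matrix(dOut, dims[1] * dims[2], dims[3]) else dOut
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(ly$gamma, each = N)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dX <- (dxhat - rep(s1 / N, each = N) - xhat * rep(s2 / N, each = N)) *
      rep(cache$ivar, each = N)
  } else {
    dX <- dxhat * rep(cache$ivar, each = N)
  }
  if (cache$isSeq) dX <- array(dX, dims)
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
}

# ---- elementwise / structural layers ---------------------------------------

reluForward <- function(A) {
  mask <- A > 0
  list(out = A * mask, cache = mask)
}

poolForward <- function(ly, A) {
  d <- dim(A); B <- d[1]; Lin <- d[2]; C <- d[3]
  Q <- (Lin - ly$size) %/% ly$stride + 1L
  out <- array(-Inf, c(B, Q, C))
  arg <- array(1L, c(B, Q, C))
  for (s in seq_len(ly$size)) {
    idx <- (seq_len(Q) - 1L) * ly$stride + s
    cand <- A[, idx, , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- s
  }
  list(out = out, cache = list(arg = arg, Lin = Lin, Q = Q))
}

poolBackward <- function(ly, cache, dOut) {
  d <- dim(dOut); B <- d[1]; C <- d[3]
  dA <- array(0, c(B, cache$Lin, C))
  for (s in seq_len(ly$size)) {
    idx <- (seq_len(cache$Q) - 1L) * ly$stride + s
    dA[, idx, ] <- dA[, idx, , drop = FALSE] + dOut * (cache$arg == s)
  }
  dA
}

dropoutForward <- function(ly, A, training) {
  if (!training || ly$rate <= 0) return(list(out = A, cache = NULL))
  mask <- array((stats::runif(length(A)) >= ly$rate) / (1 - ly$rate),
                dim = dim(A) %||% length(A))
  list(out = A * mask, cache = mask)
}

denseForward <- function(ly, X) {
  out <- X %*% ly$W
  out <- out + rep(ly$b, each = nrow(out))
  list(out = out, cache = X)
}

denseBackward <- function(ly, cache, dOut) {
  list(grads = list(W = crossprod(cache, dOut), b = colSums(dOut)),
       dX = tcrossprod(dOut, ly$W))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- whole-network passes ---------------------------------------------------

# state: list(layers = <list>, headActivation, inputLength, nTasks)
# X: (B, L, 4) array. Returns list(out = B x nTasks matrix, caches).
# Training-mode dropout draws from the current RNG stream.
nnForward <- function(state, X, training = FALSE) {
  A <- X
  caches <- vector("list", length(state$layers))
  for (i in seq_along(state$layers)) {
    ly <- state$layers[[i]]
    r <- switch(ly$kind,
      conv1d = convForward(ly, A),
      batchnorm = {
        rr <- bnForward(ly, A, training)
        state$layers[[i]] <- rr$layer  # running stats updated in training
        rr
      },
      relu = reluForward(A),
      maxpool = poolForward(ly, A),
      dropout = dropoutForward(ly, A, training),
      flatten = list(out = matrix(A, dim(A)[1], dim(A)[2] * dim(A)[3]),
                     cache = dim(A)),
      dense = denseForward(ly, A),
      output = {
        rr <- denseForward(ly, A)
        pre <- rr$out
        post <- if (state$headActivation == "sigmoid") sigmoid(pre) else pre
        list(out = post, cache = list(dense = rr$cache, post = post))
      },
      stop("unknown layer kind"))
    caches[[i]] <- r$cache
    A <- r$out
  }
  list(out = A, caches = caches, state = state)
}

# Backward pass from a gradient w.r.t. the output layer PRE-activation.
# Returns per-layer parameter gradients and the input gradient.
nnBackward <- function(state, caches, dPre) {
  n <- length(state$layers)
  grads <- vector("list", n)
  dA <- dPre
  for (i in rev(seq_len(n))) {
    ly <- state$layers[[i]]
    dA <- switch(ly$kind,
      conv1d = {
        r <- convBackward(ly, caches[[i]], dA)
        grads[[i]] <- r$grads
        r$dX
      },
      batchnorm = {
        r <- bnBackward(ly, caches[[i]], dA)
        grads[[i]] <- r$grads
        r$dX
      },
      relu = dA * caches[[i]],
      maxpool = poolBackward(ly, caches[[i]], dA),
      dropout = if (is.null(caches[[i]])) dA else dA * caches[[i]],
      flatten = array(dA, caches[[i]]),
      dense = {
        r <- denseBackward(ly, caches[[i]], dA)
        grads[[i]] <- r$grads
        r$dX
      },
      output = {
        r <- denseBackward(ly, caches[[i]]$dense, dA)
        grads[[i]] <- r$grads
        r$dX
      })
  }
  list(grads = grads, dX = dA)
}

# Convert a gradient w.r.t. the POST-activation head into one w.r.t. the
# pre-activation, using the cached head output.
headPostToPre <- function(state, caches, dPost) {
  if (state$headActivation == "sigmoid") {
    p <- caches[[length(caches)]]$post
    dPost * p * (1 - p)
  } else dPost
}

# Mean loss over batch and tasks plus the gradient w.r.t. the head
# pre-activation. Binary tasks: cross-entropy with a sigmoid head (the
# sigmoid is folded into the gradient); regression: mean squared error.
lossAndGrad <- function(post, y, taskKind) {
  n <- length(post)
  if (taskKind == "binary") {
    p <- pmin(pmax(post, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dPre <- (post - y) / n
  } else {
    loss <- mean((post - y)^2)
    dPre <- 2 * (post - y) / n
  }
  list(loss = loss, dPre = dPre)
}

evalLoss <- function(state, X, y, taskKind, batchSize = 512L) {
  n <- dim(X)[1]
  tot <- 0
  for (ix in splitBatches(n, batchSize)) {
    out <- nnForward(state, X[ix, , , drop = FALSE], training = FALSE)$out
    tot <- tot + lossAndGrad(out, y[ix, , drop = FALSE], taskKind)$loss * length(ix)
  }
  tot / n
}

splitBatches <- function(n, batchSize) {
  split(seq_len(n), ceiling(seq_len(n) / batchSize))
}
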