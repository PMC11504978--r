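# Minibatch neural-network engine on base matrix operations (BLAS-bound).
# Layers: dense, 2-D convolution (3x3, stride 1, zero padding, via im2col),
# ReLU, dropout (train-time only, inverted scaling), softmax + cross-entropy.
# Optimiser: Adam. Data layout inside the engine is columns = samples.

heInit <- function(nOut, nIn, fanIn) {
  matrix(stats::rnorm(nOut * nIn, sd = sqrt(2 / fanIn)), nOut, nIn)
}

layerDense <- function(nIn, nOut) {
  list(kind = "dense",
       W = heInit(nOut, nIn, nIn),
       b = matrix(0, nOut, 1))
}

# Convolution on an H x W x Cin feature map flattened position-major within
# channel (index = pos + (ch-1) * H*W, positions column-major). Kernel 3x3,
# stride 1, "same" zero padding. Index tables are precomputed per layer.
layerConv <- function(H, W, cIn, cOut, kernel = 3L) {
  pad <- (kernel - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  # map from unpadded to padded linear indices, per channel
  rc <- expand.grid(r = seq_len(H), c = seq_len(W))
  padPos <- (rc$c + pad - 1L) * Hp + (rc$r + pad) # linear in padded plane
  padMap <- as.vector(outer(padPos, (seq_len(cIn) - 1L) * Hp * Wp, `+`))
  # im2col: for each output position (H*W) the kernel*kernel*cIn padded rows
  offs <- expand.grid(dr = 0:(kernel - 1L), dc = 0:(kernel - 1L))
  patch <- function(p) { # p = output position (1..H*W), column-major
    r0 <- (p - 1L) %% H + 1L
    c0 <- (p - 1L) %/% H + 1L
    base <- (c0 + offs$dc - 1L) * Hp + (r0 + offs$dr) # kernel^2 padded rows
    as.vector(outer(base, (seq_len(cIn) - 1L) * Hp * Wp, `+`))
  }
  idx <- vapply(seq_len(H * W), patch, integer(kernel * kernel * cIn))
  # idx: (kernel^2 * cIn) x (H*W) indices into the padded stack
  kIn <- kernel * kernel * cIn
  list(kind = "conv",
       W = heInit(cOut, kIn, kIn),
       b = matrix(0, cOut, 1),
       H = H, Wd = W, cIn = cIn, cOut = cOut,
       nPad = Hp * Wp * cIn, padMap = padMap, idx = as.vector(idx),
       kIn = kIn, nPos = H * W)
}

layerRelu <- function() list(kind = "relu")
layerDropout <- function(rate) list(kind = "dropout", rate = rate)

forwardLayer <- function(layer, X, training) {
  switch(layer$kind,
    dense = {
      Z <- layer$W %*% X + matrix(layer$b, nrow(layer$W), ncol(X))
      list(out = Z, cache = X)
    },
    conv = {
      batch <- ncol(X)
      Xpad <- matrix(0, layer$nPad, batch)
      Xpad[layer$padMap, ] <- X
      P <- Xpad[layer$idx, , drop = FALSE]
      dim(P) <- c(layer$kIn, layer$nPos * batch)
      Z <- layer$W %*% P + layer$b[, rep.int(1L, layer$nPos * batch), drop = FALSE]
      A <- array(Z, c(layer$cOut, layer$nPos, batch))
      A <- aperm(A, c(2L, 1L, 3L))
      dim(A) <- c(layer$nPos * layer$cOut, batch)
      list(out = A, cache = P)
    },
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = mask)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- matrix(stats::runif(length(X)) >= layer$rate,
                       nrow(X), ncol(X)) / (1 - layer$rate)
        list(out = X * mask, cache = mask)
      } else {
        list(out = X, cache = NULL)
      }
    }
  )
}

backwardLayer <- function(layer, dOut, cache) {
  switch(layer$kind,
    dense = {
      list(dX = crossprod(layer$W, dOut),
           grads = list(W = dOut %*% t(cache), b = rowSums(dOut)))
    },
    conv = {
      batch <- ncol(dOut)
      A <- dOut
      dim(A) <- c(layer$nPos, layer$cOut, batch)
      A <- aperm(A, c(2L, 1L, 3L))
      dim(A) <- c(layer$cOut, layer$nPos * batch)
      dW <- A %*% t(cache)
      db <- rowSums(A)
      dP <- crossprod(layer$W, A) # kIn x (nPos*batch)
      dim(dP) <- c(layer$kIn * layer$nPos, batch)
      rs <- rowsum(dP, layer$idx) # grouped by padded row, sorted groups
      dXpad <- matrix(0, layer$nPad, batch)
      dXpad[as.integer(rownames(rs)), ] <- rs
      list(dX = dXpad[layer$padMap, , drop = FALSE],
           grads = list(W = dW, b = db))
    },
    relu = list(dX = dOut * cache, grads = NULL),
    dropout = {
      if (is.null(cache)) list(dX = dOut, grads = NULL)
      else list(dX = dOut * cache, grads = NULL)
    }
  )
}

softmaxProbs <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max), `-`)
  E <- exp(Z)
  sweep(E, 2L, colSums(E), `/`)
}

netForward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- forwardLayer(layers[[i]], X, training)
    X <- fw$out
    caches[i] <- list(fw$cache) # keep NULL entries (inference dropout)
  }
  list(logits = X, caches = caches)
}

# Y: 2 x batch one-hot. Returns mean cross-entropy and per-layer grads.
netBackward <- function(layers, caches, probs, Y) {
  batch <- ncol(Y)
  d <- (probs - Y) / batch
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- backwardLayer(layers[[i]], d, caches[[i]])
    d <- bw$dX
    grads[i] <- list(bw$grads) # keep NULL entries (activation layers)
  }
  grads
}

adamInit <- function(layers) {
  lapply(layers, function(l) {
    if (l$kind %in% c("dense", "conv"))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    layers[[i]]$W <- layers[[i]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    gb <- matrix(g$b, nrow(s$mb), 1)
    s$mb <- beta1 * s$mb + (1 - beta1) * gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
    layers[[i]]$b <- layers[[i]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

countParams <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$kind %in% c("dense", "conv")) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}
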