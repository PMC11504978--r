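# The three frame-level sex classifiers: a small backpropagation network
# (hidden 18-9-4), a deeper dropout-regularised perceptron (48-32-16-8,
# dropout 0.1), and a convolutional network (conv channels 128-128-64-32,
# 3x3 kernels, dropout 0.3) whose input is the 36-dim frame reshaped to a
# 6x6 single-channel grid. All end in a 2-way softmax; positive class = male.

CLASS_LEVELS <- c("male", "female") # column order of predicted probabilities

#' Declare a classifier architecture
#'
#' @param kind one of \code{"bpnn"}, \code{"dnn"}, \code{"cnn"}.
#' @param hidden hidden layer widths (dense nets). Defaults: bpnn
#'   \code{c(18, 9, 4)}; dnn \code{c(48, 32, 16, 8)}.
#' @param dropout dropout rate after each hidden/conv block. Defaults: bpnn 0
#'   (none), dnn 0.1, cnn 0.3.
#' @param conv_channels convolution channels per layer (cnn only), default
#'   \code{c(128, 128, 64, 32)}; 3x3 kernels, stride 1, zero padding, no
#'   pooling; a flatten + dense(2) + softmax head follows.
#' @param context_window optional cnn input mode: stack this many consecutive
#'   frames into a (context_window x 36) single-channel map instead of
#'   reshaping one frame to 6x6. NULL (default) keeps the single-frame unit.
#' @return list of class \code{"ModelSpec"}.
#' @export
modelSpec <- function(kind = c("bpnn", "dnn", "cnn"),
                      hidden = NULL, dropout = NULL,
                      conv_channels = c(128L, 128L, 64L, 32L),
                      context_window = NULL) {
  kind <- match.arg(kind)
  if (is.null(hidden))
    hidden <- switch(kind, bpnn = c(18L, 9L, 4L), dnn = c(48L, 32L, 16L, 8L),
                     cnn = integer(0))
  if (is.null(dropout))
    dropout <- switch(kind, bpnn = 0, dnn = 0.1, cnn = 0.3)
  structure(
    list(kind = kind, hidden = hidden, dropout = dropout,
         conv_channels = if (kind == "cnn") conv_channels else NULL,
         context_window = context_window, n_classes = 2L),
    class = "ModelSpec"
  )
}

#' @export
print.ModelSpec <- function(x, ...) {
  arch <- switch(x$kind,
    bpnn = paste0("dense ", paste(x$hidden, collapse = "-")),
    dnn = paste0("dense ", paste(x$hidden, collapse = "-"),
                 ", dropout ", x$dropout),
    cnn = paste0("conv3x3 ", paste(x$conv_channels, collapse = "-"),
                 ", dropout ", x$dropout))
  cat(sprintf("ModelSpec <%s>: %s -> softmax(2)\n", x$kind, arch))
  invisible(x)
}

#' Instantiate an untrained classifier
#'
#' Parameter initialisation is He-scaled Gaussian, seeded for
#' reproducibility: two builds with the same seed have identical initial
#' parameters.
#'
#' @param spec a [modelSpec()].
#' @param input_dim feature dimension per frame (default 36).
#' @param seed RNG seed for initialisation.
#' @return list of class \code{"duckNet"} with the layer stack and geometry.
#' @export
buildModel <- function(spec, input_dim = 36L, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  built <- withr::with_seed(seed, buildLayers(spec, input_dim))
  structure(
    list(spec = spec, layers = built$layers, geometry = built$geom,
         input_dim = as.integer(input_dim), seed = as.integer(seed),
         n_params = countParams(built$layers)),
    class = "duckNet"
  )
}

buildLayers <- function(spec, input_dim) {
  layers <- list()
  if (spec$kind %in% c("bpnn", "dnn")) {
    nIn <- input_dim
    for (h in spec$hidden) {
      layers <- c(layers, list(layerDense(nIn, h)), list(layerRelu()))
      if (spec$dropout > 0) layers <- c(layers, list(layerDropout(spec$dropout)))
      nIn <- h
    }
    layers <- c(layers, list(layerDense(nIn, spec$n_classes)))
    geom <- list(mode = "flat")
  } else {
    if (is.null(spec$context_window)) {
      side <- sqrt(input_dim)
      if (side != floor(side))
        stop("cnn input_dim ", input_dim, " is not a perfect square and no ",
             "context_window is set")
      H <- as.integer(side); W <- as.integer(side)
    } else {
      H <- as.integer(spec$context_window); W <- as.integer(input_dim)
    }
    cIn <- 1L
    for (ch in spec$conv_channels) {
      layers <- c(layers, list(layerConv(H, W, cIn, ch)), list(layerRelu()))
      if (spec$dropout > 0) layers <- c(layers, list(layerDropout(spec$dropout)))
      cIn <- ch
    }
    layers <- c(layers, list(layerDense(H * W * cIn, spec$n_classes)))
    geom <- list(mode = "grid", H = H, W = W)
  }
  list(layers = layers, geom = geom)
}

#' @export
print.duckNet <- function(x, ...) {
  cat(sprintf("duckNet <%s>: %d parameters, input dim %d%s\n",
              x$spec$kind, x$n_params, x$input_dim,
              if (!is.null(x$history)) sprintf(
                ", trained %d epochs (final val acc %.3f)",
                nrow(x$history), x$history$val_acc[nrow(x$history)]) else ""))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs full passes over the training frames (default 100).
#' @param batch_size minibatch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param validation_split fraction of frames held out for per-epoch
#'   validation (default 0.15); 0 disables validation.
#' @param seed RNG seed controlling shuffling, dropout and the validation
#'   split; recorded in the trained model.
#' @param stop_at_train_acc optional early stop: training ends after the
#'   first epoch whose training accuracy reaches this value (e.g. 1.0).
#' @param verbose print per-epoch progress.
#' @return list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(epochs = 100L, batch_size = 256L, lr = 1e-3,
                        validation_split = 0.15, seed = 1L,
                        stop_at_train_acc = NULL, verbose = FALSE) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!(validation_split >= 0 && validation_split < 1))
    stop("validation_split must lie in [0, 1)")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, validation_split = validation_split,
         seed = as.integer(seed), stop_at_train_acc = stop_at_train_acc,
         verbose = isTRUE(verbose)),
    class = "TrainConfig"
  )
}

labelsToOneHot <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class (", labels[1], ")")
  Y <- matrix(0, 2L, length(labels))
  Y[1L, labels == "male"] <- 1
  Y[2L, labels == "female"] <- 1
  Y
}

#' Train a classifier on normalized frame features
#'
#' Minimises 2-class cross-entropy on softmax outputs with the Adam
#' optimiser. Dropout is active only during training passes; the per-epoch
#' train/validation accuracy and loss are recorded as the training history.
#'
#' @param model an untrained (or previously trained) \code{"duckNet"}.
#' @param features num_frames x input_dim numeric matrix (z-scored).
#' @param labels character vector of "male"/"female", one per frame.
#' @param config a [trainConfig()].
#' @return the \code{"duckNet"} with fitted parameters and a
#'   \code{history} data.frame (epoch, train_loss, train_acc, val_loss,
#'   val_acc).
#' @export
trainModel <- function(model, features, labels, config = trainConfig()) {
  stopifnot(inherits(model, "duckNet"))
  features <- if (inherits(features, "FeatureMatrix")) features$values else features
  if (ncol(features) != model$input_dim)
    stop("feature width ", ncol(features), " does not match model input ",
         model$input_dim)
  Y <- labelsToOneHot(labels)
  X <- t(features) # columns = samples

  withr::with_seed(config$seed, {
    n <- ncol(X)
    nVal <- floor(config$validation_split * n)
    perm <- sample.int(n)
    valIdx <- if (nVal > 0L) perm[seq_len(nVal)] else integer(0)
    trIdx <- setdiff(perm, valIdx)
    Xtr <- X[, trIdx, drop = FALSE]; Ytr <- Y[, trIdx, drop = FALSE]
    Xval <- X[, valIdx, drop = FALSE]; Yval <- Y[, valIdx, drop = FALSE]
    nTr <- ncol(Xtr)

    layers <- model$layers
    state <- adamInit(layers)
    t <- 0L
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nTr)
      nBatch <- ceiling(nTr / config$batch_size)
      lossSum <- 0; accSum <- 0
      for (b in seq_len(nBatch)) {
        idx <- ord[(((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, nTr))]
        Xb <- Xtr[, idx, drop = FALSE]; Yb <- Ytr[, idx, drop = FALSE]
        fw <- netForward(layers, Xb, training = TRUE)
        probs <- softmaxProbs(fw$logits)
        eps <- 1e-12
        loss <- -mean(colSums(Yb * log(probs + eps)))
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        lossSum <- lossSum + loss * length(idx)
        accSum <- accSum +
          sum(max.col(t(probs), "first") == max.col(t(Yb), "first"))
        grads <- netBackward(layers, fw$caches, probs, Yb)
        t <- t + 1L
        upd <- adamStep(layers, grads, state, config$lr, t)
        layers <- upd$layers
        state <- upd$state
      }
      trainLoss <- lossSum / nTr
      trainAcc <- accSum / nTr
      if (length(valIdx)) {
        ev <- evalNet(layers, Xval, Yval)
        valLoss <- ev$loss; valAcc <- ev$acc
      } else {
        valLoss <- NA_real_; valAcc <- NA_real_
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = trainLoss,
                                  train_acc = trainAcc, val_loss = valLoss,
                                  val_acc = valAcc)
      if (config$verbose)
        message(sprintf("epoch %3d  loss %.4f acc %.4f  val %.4f/%.4f",
                        epoch, trainLoss, trainAcc, valLoss, valAcc))
      if (!is.null(config$stop_at_train_acc) &&
          trainAcc >= config$stop_at_train_acc) break
    }
    model$layers <- layers
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    model$train_config <- config
    model$trained <- TRUE
  })
  model
}

evalNet <- function(layers, X, Y) {
  probs <- softmaxProbs(netForward(layers, X, training = FALSE)$logits)
  list(
    loss = -mean(colSums(Y * log(probs + 1e-12))),
    acc = mean(max.col(t(probs), "first") == max.col(t(Y), "first"))
  )
}

#' Per-frame class probabilities
#'
#' Deterministic inference pass (dropout disabled): identical inputs give
#' identical outputs. Rows sum to 1.
#'
#' @param model a trained \code{"duckNet"}.
#' @param features num_frames x input_dim matrix (z-scored with the training
#'   statistics).
#' @return num_frames x 2 matrix with columns \code{male}, \code{female}.
#' @export
predictFrames <- function(model, features) {
  stopifnot(inherits(model, "duckNet"))
  features <- if (inherits(features, "FeatureMatrix")) features$values else features
  if (ncol(features) != model$input_dim)
    stop("feature width ", ncol(features), " does not match model input ",
         model$input_dim)
  probs <- softmaxProbs(netForward(model$layers, t(features),
                                   training = FALSE)$logits)
  out <- t(probs)
  colnames(out) <- CLASS_LEVELS
  out
}

#' Hard per-frame labels from probabilities
#'
#' @param probs num_frames x 2 probability matrix from [predictFrames()].
#' @return character vector of "male"/"female" (argmax; ties go to male,
#'   the first column).
#' @export
frameLabels <- function(probs) {
  CLASS_LEVELS[max.col(probs, ties.method = "first")]
}
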