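## The GCNSP model: graph convolution layers, trainable sparse pooling,
## hierarchical embedding, dense softmax head, composite loss, training.

## class order used throughout: index 1 = patient, index 2 = control.
.classLevels <- c("patient", "control")

#' Hyperparameters for GCNSP training
#'
#' Defaults follow the common settings the method ships with: learning rate
#' 1e-4, hidden size 64, 100 epochs, L2 penalty 1e-4, pooling ratio 0.5,
#' dropout 0.5, L1 penalty on the sparse pooling 5e-4, batch size 32 for
#' multi-site pooled training (16 is the convention for single-site
#' fine-tuning), two sparse-pooling layers, k = 10 graph neighbours.
#'
#' @param learningRate Adam step size.
#' @param hiddenSize width of both convolution layers (use 16 for
#'   interpretability runs).
#' @param epochs training epochs.
#' @param l2 L2 penalty on the convolution and dense weights (not on the
#'   pooling matrices, which carry the L1 term instead).
#' @param poolRatio node-retention ratio of each pooling layer, in (0, 1].
#' @param dropout dropout probability in [0, 1), applied to node features
#'   after the first convolution and to the graph embedding before the head.
#' @param lambdaSparse penalty factor of the L1 term on the pooling matrices.
#' @param batchSize minibatch size.
#' @param nPoolLayers number of sparse-pooling layers.
#' @param knn neighbour count of the population graph.
#' @param seed master seed for initialisation, shuffling and dropout.
#' @return a validated list of class \code{"gcnspHyper"}.
#' @export
gcnspHyper <- function(learningRate = 1e-4, hiddenSize = 64L, epochs = 100L,
                       l2 = 1e-4, poolRatio = 0.5, dropout = 0.5,
                       lambdaSparse = 5e-4, batchSize = 32L,
                       nPoolLayers = 2L, knn = 10L, seed = 1L) {
  h <- list(learningRate = learningRate, hiddenSize = as.integer(hiddenSize),
            epochs = as.integer(epochs), l2 = l2, poolRatio = poolRatio,
            dropout = dropout, lambdaSparse = lambdaSparse,
            batchSize = as.integer(batchSize),
            nPoolLayers = as.integer(nPoolLayers), knn = as.integer(knn),
            seed = as.integer(seed))
  assertThat(h$poolRatio > 0 && h$poolRatio <= 1, "poolRatio must be in (0, 1]")
  assertThat(h$dropout >= 0 && h$dropout < 1, "dropout must be in [0, 1)")
  assertThat(h$lambdaSparse >= 0, "lambdaSparse must be >= 0")
  assertThat(h$epochs >= 0 && h$batchSize >= 1 && h$hiddenSize >= 1,
             "epochs must be >= 0; batchSize and hiddenSize positive")
  class(h) <- "gcnspHyper"
  h
}

## pooled layer sizes n_i = ceiling(ratio * n_{i-1}), n_0 = N
poolSizes <- function(nNodes, ratio, nLayers) {
  sizes <- integer(nLayers)
  prev <- nNodes
  for (i in seq_len(nLayers)) {
    sizes[i] <- as.integer(ceiling(ratio * prev))
    prev <- sizes[i]
  }
  sizes
}

#' Initialise GCNSP parameters
#'
#' Weights are drawn from a symmetric uniform distribution scaled by fan-in
#' and fan-out (\eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}). Pooling matrices are
#' initialised dense; their sparsity is learned through the L1 penalty, not
#' imposed. The dense head carries no bias so that the class-activation-map
#' conservation identity is exact.
#'
#' @param nNodes number of graph nodes N (feature dimension is also N).
#' @param hyper a [gcnspHyper()] list.
#' @param pooling \code{"sparse"} (trainable pooling matrices) or
#'   \code{"mean"} (fixed node-mean readout: the plain-GCN ablation).
#' @param seed integer; defaults to \code{hyper$seed}.
#' @return parameter list with \code{w0}, \code{w1}, \code{theta} (list),
#'   \code{dense_w}; attribute \code{"thetaTrainable"} flags which pooling
#'   matrices receive gradients.
#' @export
gcnspInit <- function(nNodes, hyper = gcnspHyper(), pooling = c("sparse", "mean"),
                      seed = hyper$seed) {
  pooling <- match.arg(pooling)
  d1 <- d2 <- hyper$hiddenSize
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  withSeed(deriveSeed(seed, "init"), {
    w0 <- glorot(nNodes, d1)
    w1 <- glorot(d1, d2)
    if (pooling == "sparse") {
      sizes <- poolSizes(nNodes, hyper$poolRatio, hyper$nPoolLayers)
      prev <- c(nNodes, sizes[-length(sizes)])
      theta <- Map(function(ni, np) glorot(ni, np), sizes, prev)
      trainable <- rep(TRUE, length(theta))
    } else {
      theta <- list(matrix(1 / nNodes, 1L, nNodes))
      sizes <- 1L
      trainable <- FALSE
    }
    denseW <- glorot(sum(sizes) * d2, 2L)
    params <- list(w0 = w0, w1 = w1, theta = theta, dense_w = denseW)
    attr(params, "thetaTrainable") <- trainable
    attr(params, "pooling") <- pooling
    params
  })
}

#' One graph convolution layer
#'
#' \eqn{H^{(l+1)} = \sigma(\hat A H^{(l)} W^{(l)})} with \eqn{\hat A} the
#' renormalized adjacency.
#'
#' @param aHat N x N renormalized adjacency (see [normalizeAdjacency()]).
#' @param h N x D activation matrix.
#' @param w D x D' weight matrix.
#' @param activation \code{"relu"} or \code{"id"}.
#' @return N x D' matrix.
#' @export
gcnLayer <- function(aHat, h, w, activation = c("relu", "id")) {
  activation <- match.arg(activation)
  assertThat(ncol(aHat) == nrow(h), "aHat and H disagree in node count")
  assertThat(ncol(h) == nrow(w), "H and W disagree in feature dimension")
  out <- aHat %*% h %*% w
  if (activation == "relu") out <- pmax(out, 0)
  out
}

#' One sparse-pooling layer
#'
#' The pure linear coarsening \eqn{Z_G^i = \Theta^i_{sp} Z_G^{i-1}}; sparsity
#' of \eqn{\Theta} is driven by its L1 penalty during training.
#'
#' @param zPrev n_{i-1} x D matrix.
#' @param theta n_i x n_{i-1} pooling matrix.
#' @return n_i x D matrix.
#' @export
sparsePool <- function(zPrev, theta) {
  assertThat(ncol(theta) == nrow(zPrev), "theta and input disagree in node count")
  theta %*% zPrev
}

#' Hierarchical graph embedding
#'
#' Applies the pooling chain to the node embeddings and concatenates the
#' row-major flattenings of all pooled layers, in layer order, into the
#' final graph-level embedding vector.
#'
#' @param z N x D node embedding matrix (output of the last convolution).
#' @param thetaList list of pooling matrices chaining from N.
#' @return list with \code{zgLayers} (the pooled matrices) and \code{zg}
#'   (the concatenated embedding vector).
#' @export
hierarchicalEmbedding <- function(z, thetaList) {
  assertThat(length(thetaList) >= 1, "at least one pooling layer is required")
  layers <- vector("list", length(thetaList))
  cur <- z
  for (i in seq_along(thetaList)) {
    cur <- sparsePool(cur, thetaList[[i]])
    layers[[i]] <- cur
  }
  list(zgLayers = layers,
       zg = unlist(lapply(layers, flattenRowMajor), use.names = FALSE))
}

## seeded inverted-dropout mask
dropoutMask <- function(n, p) {
  if (p <= 0) return(NULL)
  (stats::runif(n) >= p) / (1 - p)
}

#' Forward pass of the GCNSP model
#'
#' \eqn{Z = ReLU(\hat A\, ReLU(\hat A X W^{(0)})\, W^{(1)})}, hierarchical
#' pooling, linear bias-free head, softmax. In evaluation mode
#' (\code{dropoutSeed = NULL}) the pass is deterministic; a seed enables the
#' training-time dropout placement (after convolution 1 and on the embedding
#' before the head).
#'
#' @param aHat renormalized adjacency.
#' @param x N x N node feature matrix (the subject's connectivity).
#' @param params parameter list from [gcnspInit()] or a fitted model.
#' @param dropoutSeed integer or \code{NULL} (evaluation mode).
#' @param dropout dropout probability used when a seed is given.
#' @return list: \code{probs} (patient, control), \code{logits}, \code{zg},
#'   \code{zgLayers}, \code{z}, \code{h1}, \code{pre1}, \code{pre2},
#'   \code{x} — all intermediate channel activations ("feature maps").
#' @export
gcnspForward <- function(aHat, x, params, dropoutSeed = NULL, dropout = 0) {
  assertThat(all(is.finite(x)), "non-finite entries in the feature matrix")
  masks <- NULL
  d1 <- ncol(params$w0)
  p <- nrow(params$dense_w)
  if (!is.null(dropoutSeed) && dropout > 0) {
    masks <- withSeed(dropoutSeed, list(
      h1 = matrix(dropoutMask(nrow(x) * d1, dropout), nrow(x), d1),
      zg = dropoutMask(p, dropout)))
  }
  pre1 <- aHat %*% x %*% params$w0
  h1 <- pmax(pre1, 0)
  if (!is.null(masks)) h1 <- h1 * masks$h1
  pre2 <- aHat %*% h1 %*% params$w1
  z <- pmax(pre2, 0)
  emb <- hierarchicalEmbedding(z, params$theta)
  zg <- emb$zg
  if (!is.null(masks)) zg <- zg * masks$zg
  logits <- as.vector(zg %*% params$dense_w)
  mx <- max(logits)
  pr <- exp(logits - mx)
  pr <- pr / sum(pr)
  names(pr) <- names(logits) <- .classLevels
  list(probs = pr, logits = logits, zg = zg, zgLayers = emb$zgLayers,
       z = z, h1 = h1, pre1 = pre1, pre2 = pre2, x = x)
}

#' Composite training loss
#'
#' \code{total = class + sparse + l2}: standard cross-entropy on the
#' predicted class probabilities, the L1 penalty
#' \eqn{\lambda \sum_i \|\Theta^i_{sp}\|_1} on the trainable pooling
#' matrices, and the L2 penalty on the convolution and head weights.
#'
#' @param probs length-2 probability vector (or matrix, subjects in rows).
#' @param yTrue true labels ("patient"/"control" or 1/2 indices).
#' @param params parameter list (for the penalty terms); \code{NULL} for a
#'   pure classification loss.
#' @param lambdaSparse,l2 penalty factors.
#' @return list of class \code{"gcnspLoss"}: \code{total},
#'   \code{class_loss}, \code{sparse_loss}, \code{l2_loss}.
#' @export
gcnspLoss <- function(probs, yTrue, params = NULL, lambdaSparse = 5e-4,
                      l2 = 1e-4) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  yIdx <- if (is.character(yTrue)) match(yTrue, .classLevels) else as.integer(yTrue)
  assertThat(!anyNA(yIdx) && all(yIdx %in% 1:2), "invalid true labels")
  pTrue <- probs[cbind(seq_len(nrow(probs)), yIdx)]
  classLoss <- mean(-log(pmax(pTrue, 1e-12)))
  sparseLoss <- 0
  l2Loss <- 0
  if (!is.null(params)) {
    trainable <- attr(params, "thetaTrainable")
    if (is.null(trainable)) trainable <- rep(TRUE, length(params$theta))
    sparseLoss <- lambdaSparse *
      sum(vapply(params$theta[trainable], function(t) sum(abs(t)), 0))
    l2Loss <- l2 * (sum(params$w0^2) + sum(params$w1^2) + sum(params$dense_w^2))
  }
  out <- list(total = classLoss + sparseLoss + l2Loss, class_loss = classLoss,
              sparse_loss = sparseLoss, l2_loss = l2Loss)
  class(out) <- "gcnspLoss"
  out
}

## Precompute the cube of A_hat %*% X_b for a set of subjects.
precomputeAX <- function(ce, aHat, ids) {
  n <- nRois(ce)
  ax <- array(0, c(n, n, length(ids)))
  for (b in seq_along(ids))
    ax[, , b] <- aHat %*% connMatrix(ce, ids[b])
  ax
}

#' Train a GCNSP (or plain-GCN) model
#'
#' Minibatch Adam on the composite loss. Shuffling, initialisation and
#' dropout all derive from the seed, so training with identical seed and
#' data is bit-reproducible. The optional callback observes every epoch
#' (signature \code{function(epoch, params, historyRow)}), which is what the
#' transfer protocol's optimal-epoch selection hooks into.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}: the training data (plus,
#'   optionally, validation subjects).
#' @param aHat renormalized adjacency of the shared population graph.
#' @param hyper a [gcnspHyper()] list.
#' @param model \code{"gcnsp"} (trainable sparse pooling) or \code{"gcn"}
#'   (fixed node-mean readout ablation).
#' @param validationIds subjects held out of the gradient updates but scored
#'   every epoch.
#' @param initParams optional warm-start parameters (transfer learning);
#'   default fresh initialisation.
#' @param callback optional per-epoch observer.
#' @param seed integer; defaults to \code{hyper$seed}.
#' @return a \linkS4class{GcnspModel}.
#' @export
trainGcnsp <- function(ce, aHat, hyper = gcnspHyper(),
                       model = c("gcnsp", "gcn"), validationIds = NULL,
                       initParams = NULL, callback = NULL, seed = hyper$seed) {
  model <- match.arg(model)
  ids <- subjectIds(ce)
  trainIds <- setdiff(ids, validationIds)
  assertThat(length(trainIds) > 0, "empty training set")
  yAll <- match(groupLabels(ce), .classLevels) - 1L
  names(yAll) <- ids
  if (length(unique(yAll[trainIds])) < 2)
    stop("training set contains a single class", call. = FALSE)

  n <- nRois(ce)
  params <- if (is.null(initParams)) {
    gcnspInit(n, hyper, pooling = if (model == "gcnsp") "sparse" else "mean",
              seed = seed)
  } else initParams
  trainable <- attr(params, "thetaTrainable")

  axTrain <- precomputeAX(ce, aHat, trainIds)
  axVal <- if (length(validationIds)) precomputeAX(ce, aHat, validationIds)
           else array(0, c(0, 0, 0))
  keepSnaps <- !is.null(callback)

  res <- withSeed(deriveSeed(seed, "train"),
    cpp_gcnsp_train(aHat, axTrain, as.integer(yAll[trainIds]),
                    axVal, as.integer(yAll[validationIds]),
                    params$w0, params$w1, params$theta, params$dense_w,
                    as.integer(trainable), hyper$learningRate, hyper$l2,
                    hyper$lambdaSparse, hyper$dropout, hyper$batchSize,
                    hyper$epochs, keepSnaps))
  history <- as.data.frame(res$history)
  names(history) <- c("epoch", "train_loss", "train_class_loss", "train_acc",
                      "val_loss", "val_acc")
  outParams <- res$params
  attributes(outParams) <- c(attributes(outParams),
                             attributes(params)[c("thetaTrainable", "pooling")])
  if (keepSnaps) {
    for (epoch in seq_len(hyper$epochs)) {
      snap <- res$snapshots[[epoch]]
      attributes(snap) <- c(attributes(snap),
                            attributes(params)[c("thetaTrainable", "pooling")])
      callback(epoch, snap, history[epoch, ])
    }
  }
  new("GcnspModel", params = outParams, aHat = aHat,
      hyper = c(unclass(hyper), list(model = model)),
      history = history, fitIds = trainIds)
}

#' Score subjects with a fitted model
#'
#' @param model a \linkS4class{GcnspModel} (or a bare parameter list plus
#'   \code{aHat}).
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param ids subjects to score (default all).
#' @return data.frame: \code{subject_id}, \code{score} (probability of the
#'   patient class), \code{predicted}, \code{label}.
#' @export
predictGcnsp <- function(model, ce, ids = subjectIds(ce)) {
  params <- modelParams(model)
  ax <- precomputeAX(ce, model@aHat, ids)
  r <- cpp_gcnsp_batch(model@aHat, ax, params$w0, params$w1, params$theta,
                       params$dense_w, rep(-1L, length(ids)),
                       array(0, c(0, 0, 0)), matrix(0, 0, 0), FALSE)
  score <- r$probs[, 1]
  data.frame(subject_id = ids, score = score,
             predicted = ifelse(score >= 0.5, "patient", "control"),
             label = groupLabels(ce)[match(ids, subjectIds(ce))],
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a portable container holding all parameter matrices,
#' hyperparameters, the training-fold graph and the seed; it round-trips
#' bit-exactly.
#'
#' @param model a \linkS4class{GcnspModel}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the \linkS4class{GcnspModel}.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, aHat = model@aHat, hyper = model@hyper,
               history = model@history, fitIds = model@fitIds,
               hash = configHash(model@params)), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  assertThat(identical(configHash(x$params), x$hash),
             "checkpoint corrupted: parameter hash mismatch")
  new("GcnspModel", params = x$params, aHat = x$aHat, hyper = x$hyper,
      history = x$history, fitIds = x$fitIds)
}
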