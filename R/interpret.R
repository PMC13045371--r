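## Interpretability: layer feature maps, network-overlap percentages,
## class activation maps down to single edges, group-difference t/KDE
## summaries, and graph-shuffle controls.

#' Average per-channel feature maps of a convolution layer
#'
#' The feature map of a layer is its output: an N x channels activation
#' matrix per subject. This extracts them in evaluation mode and averages
#' elementwise over the given subjects.
#'
#' @param model a \linkS4class{GcnspModel}.
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param ids non-empty subject set.
#' @param layer \code{"gcn1"} or \code{"gcn2"}.
#' @return list of class \code{"featureMapSet"}: \code{layer}, \code{maps}
#'   (nodes x channels matrix of averaged activations),
#'   \code{subjectCount}.
#' @export
extractFeatureMaps <- function(model, ce, ids = subjectIds(ce),
                               layer = c("gcn1", "gcn2")) {
  layer <- match.arg(layer)
  assertThat(length(ids) > 0, "empty subject set")
  params <- modelParams(model)
  acc <- NULL
  for (id in ids) {
    fw <- gcnspForward(model@aHat, connMatrix(ce, id), params)
    m <- if (layer == "gcn1") fw$h1 else fw$z
    acc <- if (is.null(acc)) m else acc + m
  }
  out <- list(layer = layer, maps = acc / length(ids),
              subjectCount = length(ids))
  class(out) <- "featureMapSet"
  out
}

#' Network association of feature-map channels
#'
#' For each channel, the top fraction of nodes by absolute activation is
#' its "discriminative region". A channel is associated with the network
#' holding the largest share of that region — raw, or corrected for network
#' size (the raw share divided by the network's node-count fraction). The
#' per-network percentage is the fraction of channels associated with it.
#'
#' @param fm a feature-map set from [extractFeatureMaps()], or a bare
#'   nodes x channels matrix.
#' @param partition data.frame \code{roi_id}, \code{network} covering the
#'   feature map's nodes (see [makePartition()]).
#' @param topFraction fraction of nodes per channel treated as the
#'   discriminative region, in (0, 1]; default 0.1.
#' @return data.frame: \code{network}, \code{nNodes},
#'   \code{pctChannelsRaw}, \code{pctChannelsCorrected}.
#' @export
networkOverlap <- function(fm, partition, topFraction = 0.1) {
  assertThat(topFraction > 0 && topFraction <= 1,
             "topFraction must be in (0, 1]")
  maps <- if (is.list(fm)) fm$maps else fm
  n <- nrow(maps)
  assertThat(nrow(partition) == n, "partition does not cover the feature map")
  nets <- unique(partition$network)
  sizes <- vapply(nets, function(x) sum(partition$network == x), 0L)
  nTop <- as.integer(ceiling(topFraction * n))
  assocRaw <- assocCor <- character(ncol(maps))
  for (ch in seq_len(ncol(maps))) {
    top <- order(-abs(maps[, ch]), seq_len(n))[seq_len(nTop)]
    raw <- vapply(nets, function(x) mean(partition$network[top] == x), 0)
    cor <- raw / (sizes / n)
    assocRaw[ch] <- nets[which.max(raw)]
    assocCor[ch] <- nets[which.max(cor)]
  }
  data.frame(network = nets, nNodes = sizes,
             pctChannelsRaw = 100 * vapply(nets, function(x) mean(assocRaw == x), 0),
             pctChannelsCorrected = 100 * vapply(nets, function(x) mean(assocCor == x), 0),
             row.names = NULL)
}

#' Class activation map at the embedding level
#'
#' With a bias-free linear head the pre-softmax class score decomposes
#' exactly over the graph embedding: \eqn{S_c = \sum_x w^c_x z_g[x]}. The
#' per-entry contributions are the embedding-level class activation map;
#' their sum reproduces the class score to machine precision.
#'
#' @param params a parameter list (or \linkS4class{GcnspModel}).
#' @param forward the output of [gcnspForward()] for one subject
#'   (evaluation mode).
#' @param classId \code{"patient"} (default) or \code{"control"}.
#' @return list of class \code{"classActivationMap"}: \code{classId},
#'   \code{embeddingScores}, \code{classScore}, \code{layerScores}
#'   (per pooled layer, unflattened to n_i x D2).
#' @export
camEmbedding <- function(params, forward, classId = "patient") {
  if (is(params, "GcnspModel")) params <- modelParams(params)
  if (!is.null(params$dense_b) && any(params$dense_b != 0))
    stop("dense head carries a bias: the CAM conservation identity would not hold",
         call. = FALSE)
  cIdx <- match(classId, .classLevels)
  assertThat(!is.na(cIdx), "classId must be 'patient' or 'control'")
  scores <- params$dense_w[, cIdx] * forward$zg
  d2 <- ncol(forward$z)
  layerScores <- list()
  off <- 0L
  for (i in seq_along(forward$zgLayers)) {
    ni <- nrow(forward$zgLayers[[i]])
    layerScores[[i]] <- unflattenRowMajor(scores[off + seq_len(ni * d2)], ni, d2)
    off <- off + ni * d2
  }
  out <- list(classId = classId, embeddingScores = scores,
              classScore = unname(forward$logits[cIdx]),
              layerScores = layerScores)
  class(out) <- "classActivationMap"
  out
}

#' Backproject an embedding-level CAM to the original nodes
#'
#' Each pooled layer's score matrix is carried back to node space through
#' the transposes of the (purely linear) pooling chain, then summed across
#' layers and channels.
#'
#' @param cam output of [camEmbedding()].
#' @param thetaList the model's pooling matrices.
#' @return numeric length-N node score vector.
#' @export
camNodes <- function(cam, thetaList) {
  nodeScores <- NULL
  proj <- NULL  # N x n_i backprojection, grown one layer at a time
  for (i in seq_along(cam$layerScores)) {
    proj <- if (is.null(proj)) t(thetaList[[i]]) else proj %*% t(thetaList[[i]])
    contrib <- rowSums(proj %*% cam$layerScores[[i]])
    nodeScores <- if (is.null(nodeScores)) contrib else nodeScores + contrib
  }
  nodeScores
}

#' Edge-level class activation by gradient-times-input
#'
#' The contribution of each connectivity entry to the pre-softmax class
#' score: \eqn{\partial S_c/\partial X_{ij} \cdot X_{ij}}, computed by
#' backpropagating the class score through the (evaluation-mode) network,
#' symmetrized and zero-diagonal. For a network operating in its linear
#' regime the attributions sum exactly to \eqn{S_c}.
#'
#' @param model a \linkS4class{GcnspModel} (or parameter list; then supply
#'   \code{aHat}).
#' @param x the subject's N x N feature matrix.
#' @param classId \code{"patient"} (default) or \code{"control"}.
#' @param aHat renormalized adjacency if \code{model} is a bare list.
#' @return N x N symmetric attribution matrix with zero diagonal.
#' @export
camEdges <- function(model, x, classId = "patient", aHat = NULL) {
  if (is(model, "GcnspModel")) { params <- modelParams(model); aHat <- model@aHat }
  else params <- model
  cIdx <- match(classId, .classLevels)
  fw <- gcnspForward(aHat, x, params)
  d2 <- ncol(fw$z)
  ## seed the backward pass with dS_c (a one-hot on the logits)
  dzg <- params$dense_w[, cIdx]
  nTheta <- length(params$theta)
  dZG <- list(); off <- 0L
  for (i in seq_len(nTheta)) {
    ni <- nrow(fw$zgLayers[[i]])
    dZG[[i]] <- unflattenRowMajor(dzg[off + seq_len(ni * d2)], ni, d2)
    off <- off + ni * d2
  }
  g <- dZG[[nTheta]]
  for (i in rev(seq_len(nTheta))) {
    gPrev <- t(params$theta[[i]]) %*% g
    if (i > 1) g <- dZG[[i - 1]] + gPrev else dZ <- gPrev
  }
  dP2 <- dZ * (fw$pre2 > 0)
  dH1 <- aHat %*% (dP2 %*% t(params$w1))
  dP1 <- dH1 * (fw$pre1 > 0)
  dX <- aHat %*% (dP1 %*% t(params$w0))
  symmetrizeZeroDiag(dX * x)
}

#' Top discriminative edges
#'
#' Ranks the upper-triangle edges by score and returns the top
#' \code{ceiling(fraction * E)}; ties resolve lexicographically by (i, j).
#'
#' @param edgeScores N x N symmetric score matrix.
#' @param fraction fraction of edges to keep, in (0, 1]; default 0.01
#'   (the top 1%).
#' @return data.frame \code{i}, \code{j}, \code{score}, sorted by
#'   decreasing score.
#' @export
topEdges <- function(edgeScores, fraction = 0.01) {
  assertThat(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  n <- nrow(edgeScores)
  ut <- which(upper.tri(edgeScores), arr.ind = TRUE)
  sc <- edgeScores[upper.tri(edgeScores)]
  ord <- order(-sc, ut[, 1], ut[, 2])
  keep <- ord[seq_len(as.integer(ceiling(fraction * length(sc))))]
  data.frame(i = ut[keep, 1], j = ut[keep, 2], score = sc[keep],
             row.names = NULL)
}

#' Within/between-network mean edge weights
#'
#' Averages the scores of the selected edges within each network-pair
#' block. Blocks containing none of the selected edges are reported as
#' \code{NA} (missing), not zero.
#'
#' @param edges data.frame \code{i}, \code{j}, \code{score} (e.g. from
#'   [topEdges()]).
#' @param partition data.frame \code{roi_id}, \code{network}.
#' @return symmetric networks x networks matrix of mean scores.
#' @export
networkWeights <- function(edges, partition) {
  nets <- unique(partition$network)
  w <- matrix(NA_real_, length(nets), length(nets),
              dimnames = list(nets, nets))
  cnt <- matrix(0L, length(nets), length(nets))
  net <- match(partition$network, nets)
  for (r in seq_len(nrow(edges))) {
    a <- net[edges$i[r]]; b <- net[edges$j[r]]
    lo <- min(a, b); hi <- max(a, b)
    if (cnt[lo, hi] == 0L) w[lo, hi] <- 0
    w[lo, hi] <- w[lo, hi] + edges$score[r]
    cnt[lo, hi] <- cnt[lo, hi] + 1L
  }
  nz <- cnt > 0
  w[nz] <- w[nz] / cnt[nz]
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

#' Elementwise two-sample t statistics between groups
#'
#' Pooled-variance two-sample t on each element of a map (feature map or
#' connectivity), patients minus controls, with a kernel-density summary of
#' the t distribution. Elements with zero pooled variance get t = 0 with a
#' warning.
#'
#' @param patients,controls matrices with one column per subject (rows are
#'   map elements), at least 2 subjects each.
#' @param grid optional evaluation grid for the density.
#' @return list of class \code{"groupDiffDistribution"}: \code{t_values},
#'   \code{density} (data.frame \code{grid}, \code{density}).
#' @export
groupTTest <- function(patients, controls, grid = NULL) {
  assertThat(ncol(patients) >= 2 && ncol(controls) >= 2,
             "need at least two subjects per group")
  x <- t(cbind(patients, controls))
  tv <- colTstats(x, c(rep(TRUE, ncol(patients)), rep(FALSE, ncol(controls))))
  if (any(apply(x, 2, stats::var) == 0))
    warning("elements with zero pooled variance: t set to 0")
  out <- list(t_values = tv, density = kdeDensity(tv, grid))
  class(out) <- "groupDiffDistribution"
  out
}

#' Gaussian kernel density estimate
#'
#' Scott's rule-of-thumb bandwidth with a 1e-6 floor (degenerate constant
#' input included); evaluated on the supplied grid or on an automatic grid
#' wide enough that the trapezoidal integral is 1 to within 1e-3.
#'
#' @param x numeric sample, length >= 2.
#' @param grid evaluation points; default \code{seq(min - 5h, max + 5h,
#'   length.out = 512)}.
#' @param bandwidth override the bandwidth.
#' @return data.frame \code{grid}, \code{density}.
#' @export
kdeDensity <- function(x, grid = NULL, bandwidth = NULL) {
  assertThat(length(x) >= 2, "need at least two values")
  h <- bandwidth
  if (is.null(h)) h <- tryCatch(stats::bw.nrd(x), error = function(e) 0)
  h <- max(h, 1e-6)
  if (is.null(grid))
    grid <- seq(min(x) - 5 * h, max(x) + 5 * h, length.out = 512L)
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - x) / h)) / h, 0)
  data.frame(grid = grid, density = dens)
}

#' Shuffle a population graph (control analysis)
#'
#' \code{"adjacency"} mode permutes the upper-triangle entries (destroying
#' the degree sequence but preserving the edge weight multiset) and
#' re-symmetrizes. \code{"node_order"} mode applies one random node
#' permutation to rows and columns, preserving the graph up to relabeling.
#'
#' @param g a \linkS4class{KnnGraph}.
#' @param mode \code{"adjacency"} or \code{"node_order"}.
#' @param seed integer.
#' @return a \linkS4class{KnnGraph} with the shuffled adjacency.
#' @export
shuffleAdjacency <- function(g, mode = c("adjacency", "node_order"), seed = 1L) {
  mode <- match.arg(mode)
  a <- adjacency(g)
  withSeed(deriveSeed(seed, paste0("shuffle_", mode)), {
    if (mode == "adjacency") {
      v <- a[upper.tri(a)]
      out <- matrix(0, nrow(a), ncol(a))
      out[upper.tri(out)] <- sample(v)
      out <- out + t(out)
    } else {
      p <- sample(nrow(a))
      out <- a[p, p]
    }
    new("KnnGraph", adjacency = out, k = g@k, weighting = g@weighting)
  })
}
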