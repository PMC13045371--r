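#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' ConnectomeExperiment: labelled, site-tagged connectivity matrices
#'
#' The universal sample container of the package: a
#' \linkS4class{SummarizedExperiment} whose single assay \code{"z"} holds one
#' column per subject, each column the column-major vectorization of that
#' subject's N x N Fisher-z connectivity matrix. \code{colData} carries
#' \code{subject_id}, \code{site} and \code{label} (\code{"patient"} or
#' \code{"control"}); \code{metadata(x)$roi_ids} carries the shared ROI order.
#'
#' Validity requires: every matrix symmetric (1e-8), zero diagonal, all
#' finite; labels restricted to the patient/control vocabulary; non-empty
#' site strings.
#'
#' @seealso [ConnectomeExperiment()] for construction from a list of
#'   matrices, [connMatrix()], [siteIndex()], [regressOutSite()].
#' @export
setClass("ConnectomeExperiment", contains = "SummarizedExperiment")

setValidity("ConnectomeExperiment", function(object) {
  cd <- colData(object)
  need <- c("subject_id", "site", "label")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!all(cd$label %in% c("patient", "control")))
    return("labels must be 'patient' or 'control'")
  if (any(!nzchar(cd$site)))
    return("site identifiers must be non-empty")
  if (anyDuplicated(cd$subject_id))
    return("duplicated subject_id")
  n <- nRois(object)
  if (nrow(object) != n * n)
    return("assay row count is not a perfect square of the ROI count")
  z <- SummarizedExperiment::assay(object, "z")
  if (ncol(z) > 0) {
    if (any(!is.finite(z))) return("non-finite connectivity values")
    for (j in seq_len(ncol(z))) {
      m <- matrix(z[, j], n, n)
      if (max(abs(m - t(m))) > 1e-8)
        return(sprintf("connectivity matrix of subject '%s' is asymmetric",
                       cd$subject_id[j]))
      if (any(diag(m) != 0))
        return(sprintf("connectivity matrix of subject '%s' has nonzero diagonal",
                       cd$subject_id[j]))
    }
  }
  TRUE
})

#' Construct a ConnectomeExperiment
#'
#' @param matrices named list of N x N Fisher-z connectivity matrices, one
#'   per subject (names are subject ids, or supply \code{subjectIds}).
#' @param site character vector of site identifiers, one per subject.
#' @param label character vector, \code{"patient"}/\code{"control"}.
#' @param roiIds optional ROI identifiers; default taken from the first
#'   matrix's dimnames or \code{ROI1..ROIN}.
#' @param subjectIds optional subject identifiers.
#' @return a \linkS4class{ConnectomeExperiment}.
#' @examples
#' m <- matrix(0, 4, 4)
#' ce <- ConnectomeExperiment(list(a = m, b = m),
#'                            site = c("S1", "S1"),
#'                            label = c("patient", "control"))
#' nRois(ce)
#' @export
ConnectomeExperiment <- function(matrices, site, label, roiIds = NULL,
                                 subjectIds = names(matrices)) {
  assertThat(length(matrices) > 0, "no subjects supplied")
  if (is.null(subjectIds))
    subjectIds <- sprintf("sub%04d", seq_along(matrices))
  n <- nrow(matrices[[1]])
  if (is.null(roiIds)) {
    roiIds <- rownames(matrices[[1]])
    if (is.null(roiIds)) roiIds <- sprintf("ROI%03d", seq_len(n))
  }
  for (m in matrices)
    assertThat(is.matrix(m) && all(dim(m) == n),
               "all connectivity matrices must share the same ROI set")
  z <- vapply(matrices, as.vector, numeric(n * n))
  dim(z) <- c(n * n, length(matrices))
  colnames(z) <- subjectIds
  se <- SummarizedExperiment(
    assays  = list(z = z),
    colData = DataFrame(subject_id = subjectIds, site = as.character(site),
                        label = as.character(label), row.names = subjectIds),
    metadata = list(roi_ids = roiIds))
  new("ConnectomeExperiment", se)
}

#' @describeIn ConnectomeExperiment-class number of ROIs (graph nodes)
#' @param x a ConnectomeExperiment
#' @export
nRois <- function(x) {
  n <- metadata(x)$roi_ids
  if (!is.null(n)) return(length(n))
  as.integer(round(sqrt(nrow(x))))
}

#' @describeIn ConnectomeExperiment-class ROI identifiers
#' @export
roiIds <- function(x) metadata(x)$roi_ids

#' @describeIn ConnectomeExperiment-class subject identifiers
#' @export
subjectIds <- function(x) colData(x)$subject_id

#' @describeIn ConnectomeExperiment-class site of each subject
#' @export
sites <- function(x) colData(x)$site

#' @describeIn ConnectomeExperiment-class diagnostic label of each subject
#' @export
groupLabels <- function(x) colData(x)$label

#' @describeIn ConnectomeExperiment-class site -> subject positions mapping
#' @export
siteIndex <- function(x) split(seq_len(ncol(x)), sites(x))

#' Extract one subject's connectivity matrix
#'
#' @param x a \linkS4class{ConnectomeExperiment}.
#' @param subject subject id (character) or column index.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
connMatrix <- function(x, subject) {
  n <- nRois(x)
  m <- matrix(SummarizedExperiment::assay(x, "z")[, subject], n, n)
  dimnames(m) <- list(roiIds(x), roiIds(x))
  m
}

setMethod("show", "ConnectomeExperiment", function(object) {
  cat(sprintf("ConnectomeExperiment: %d subjects, %d ROIs, %d site(s)\n",
              ncol(object), nRois(object), length(unique(sites(object)))))
  tab <- table(sites(object), groupLabels(object))
  print(tab)
  invisible(object)
})

#' KnnGraph: the shared population graph
#'
#' A K-nearest-neighbour graph over ROIs built from the training-fold mean
#' connectivity. Adjacency is symmetric (union symmetrization), nonnegative,
#' zero-diagonal; weights are binary or similarity (1 - correlation
#' distance, floored at 0).
#'
#' @slot adjacency N x N numeric matrix.
#' @slot k integer neighbour count used at construction.
#' @slot weighting \code{"binary"} or \code{"similarity"}.
#' @seealso [buildKnnGraph()], [normalizeAdjacency()]
#' @export
setClass("KnnGraph",
         representation(adjacency = "matrix", k = "integer",
                        weighting = "character"))

setValidity("KnnGraph", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (any(diag(a) != 0)) return("adjacency diagonal must be zero")
  if (any(a < 0)) return("adjacency must be nonnegative")
  if (max(abs(a - t(a))) > 1e-10) return("adjacency must be symmetric")
  if (object@k < 1L || object@k >= nrow(a)) return("k out of range")
  TRUE
})

#' @describeIn KnnGraph-class the adjacency matrix
#' @param x a KnnGraph
#' @export
adjacency <- function(x) x@adjacency

setMethod("show", "KnnGraph", function(object) {
  a <- object@adjacency
  cat(sprintf("KnnGraph: %d nodes, %d undirected edges (k = %d, %s weights)\n",
              nrow(a), sum(a[upper.tri(a)] > 0), object@k, object@weighting))
  invisible(object)
})

#' GcnspModel: a fitted graph-convolution model with sparse pooling
#'
#' Bundles the trained parameter set, the population graph it was trained
#' on, the hyperparameters, and the per-epoch training history.
#'
#' @slot params list with elements \code{w0}, \code{w1}, \code{theta}
#'   (list of pooling matrices), \code{dense_w}, and attributes recording
#'   dimensions and which pooling matrices are trainable.
#' @slot aHat the renormalized adjacency the model convolves on.
#' @slot hyper hyperparameter list (see [gcnspHyper()]).
#' @slot history data.frame with one row per epoch (losses, accuracies).
#' @slot fitIds character; subject ids whose data influenced the fit
#'   (leakage audit trail).
#' @export
setClass("GcnspModel",
         representation(params = "list", aHat = "matrix", hyper = "list",
                        history = "data.frame", fitIds = "character"))

setMethod("show", "GcnspModel", function(object) {
  p <- object@params
  npar <- sum(vapply(c(list(p$w0, p$w1, p$dense_w), p$theta), length, 1L))
  cat(sprintf("GcnspModel: %d nodes, hidden %d, %d pooling layer(s), %d parameters\n",
              nrow(object@aHat), ncol(p$w0), length(p$theta), npar))
  if (nrow(object@history) > 0) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs; final train loss %.4f, accuracy %.3f\n",
                nrow(object@history), last$train_loss, last$train_acc))
  }
  invisible(object)
})

#' @describeIn GcnspModel-class trained parameter list
#' @param x a GcnspModel
#' @export
modelParams <- function(x) x@params

#' @describeIn GcnspModel-class per-epoch training history
#' @export
trainingHistory <- function(x) x@history
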