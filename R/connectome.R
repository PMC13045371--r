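## Functional-connectivity graph construction: Fisher-z connectivity,
## site regression, population K-NN graph, renormalized adjacency.

#' Fisher-z connectivity from an ROI time series
#'
#' Computes pairwise Pearson correlations between ROI time series and maps
#' them through the variance-stabilizing Fisher transform
#' \eqn{z = \mathrm{atanh}(r)}. The self-correlation diagonal is fixed at 0
#' (atanh(1) diverges) and off-diagonal \eqn{|r|} is clipped to 0.999999
#' before the transform so features stay bounded.
#'
#' @param ts T x N numeric matrix, timepoints by ROIs; column names are ROI
#'   ids if present. T >= 3, N >= 2, no missing values.
#' @return N x N symmetric Fisher-z matrix with zero diagonal.
#' @examples
#' set.seed(1)
#' z <- fisherConnectivity(matrix(rnorm(200), 50, 4))
#' @export
fisherConnectivity <- function(ts) {
  assertThat(is.matrix(ts) && nrow(ts) >= 3 && ncol(ts) >= 2,
             "time series must be a T x N matrix with T >= 3, N >= 2")
  assertThat(all(is.finite(ts)), "time series contains missing/non-finite values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance ROI time series: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -0.999999), 0.999999)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(colnames(ts), colnames(ts))
  z
}

#' Regress acquisition-site effects out of connectivity
#'
#' For every edge independently, an ordinary-least-squares fit of the
#' Fisher-z value on one-hot site indicators is estimated on the subjects in
#' \code{fitIds} only; the fitted site effect (each site's mean minus the
#' grand mean over \code{fitIds}) is then subtracted from \emph{all}
#' subjects of that site, including held-out ones. Fitting on the training
#' fold only prevents information from test subjects leaking into the
#' harmonization.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param fitIds subject ids the site model is estimated on. Must span at
#'   least two sites and cover every site present in \code{ce}.
#' @return a \linkS4class{ConnectomeExperiment} with adjusted matrices; the
#'   attribute \code{"fitIds"} records the audit trail of the fit.
#' @export
regressOutSite <- function(ce, fitIds = subjectIds(ce)) {
  fitIds <- as.character(fitIds)
  assertThat(all(fitIds %in% subjectIds(ce)), "unknown subject id in fitIds")
  site <- sites(ce)
  fitPos <- match(fitIds, subjectIds(ce))
  fitSites <- unique(site[fitPos])
  assertThat(length(fitSites) >= 2,
             "site regression needs subjects from at least two sites")
  missing <- setdiff(unique(site), fitSites)
  if (length(missing))
    stop("cannot estimate site effect for site(s) absent from fitIds: ",
         paste(missing, collapse = ", "), call. = FALSE)
  z <- SummarizedExperiment::assay(ce, "z")
  grand <- rowMeans(z[, fitPos, drop = FALSE])
  out <- z
  for (s in fitSites) {
    sFit <- fitPos[site[fitPos] == s]
    effect <- rowMeans(z[, sFit, drop = FALSE]) - grand
    cols <- which(site == s)
    out[, cols] <- out[, cols, drop = FALSE] - effect
  }
  ## the diagonal entries are all zero and identical across subjects, so the
  ## fitted effect there is exactly zero: symmetry and zero diagonal survive.
  res <- ce
  SummarizedExperiment::assay(res, "z") <- out
  attr(res, "fitIds") <- fitIds
  res
}

#' Mean connectivity over a subject set
#'
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param ids non-empty set of subject ids (default: all).
#' @return N x N symmetric mean Fisher-z matrix.
#' @export
meanConnectivity <- function(ce, ids = subjectIds(ce)) {
  ids <- as.character(ids)
  assertThat(length(ids) > 0, "mean connectivity over an empty subject set")
  assertThat(all(ids %in% subjectIds(ce)), "unknown subject id")
  n <- nRois(ce)
  m <- matrix(rowMeans(SummarizedExperiment::assay(ce, "z")[, ids, drop = FALSE]), n, n)
  dimnames(m) <- list(roiIds(ce), roiIds(ce))
  m
}

## Correlation distance between node signals (rows of the mean connectivity)
## with the two self-connectivity entries masked out of each pair.
correlationDistance <- function(meanConn) {
  n <- nrow(meanConn)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      d[i, j] <- d[j, i] <- 1 - stats::cor(meanConn[i, keep], meanConn[j, keep])
    }
  }
  d
}

#' Build the population K-nearest-neighbour graph
#'
#' Nodes are ROIs; the distance between nodes i and j is the correlation
#' distance \eqn{1 - \mathrm{cor}} between their connectivity profiles (rows
#' of the training-fold mean connectivity, with the two entries touching the
#' zeroed diagonal masked). Each node selects its k smallest-distance
#' neighbours (ties broken toward the lower node index); the edge set is the
#' union over both endpoints' selections, giving a symmetric graph.
#'
#' @param meanConn N x N mean connectivity (see [meanConnectivity()]).
#' @param k neighbours per node, 1 <= k < N. Default 10.
#' @param weighting \code{"binary"} (default) or \code{"similarity"}
#'   (weight \eqn{\max(0, 1 - d)}).
#' @return a \linkS4class{KnnGraph}.
#' @export
buildKnnGraph <- function(meanConn, k = 10L, weighting = c("binary", "similarity")) {
  weighting <- match.arg(weighting)
  assertThat(isSymmetricTol(meanConn, 1e-8), "mean connectivity must be symmetric")
  n <- nrow(meanConn)
  k <- as.integer(k)
  assertThat(k >= 1L && k < n, sprintf("k must satisfy 1 <= k < N = %d", n))
  d <- correlationDistance(meanConn)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ## order by distance, ties toward the lower node index (order() is stable)
    sel <- cand[order(d[i, cand])][seq_len(k)]
    a[i, sel] <- if (weighting == "binary") 1 else pmax(0, 1 - d[i, sel])
  }
  ## union symmetrization: keep an edge if either endpoint selected it
  au <- pmax(a, t(a))
  new("KnnGraph", adjacency = au, k = k, weighting = weighting)
}

#' Renormalized adjacency for graph convolution
#'
#' Computes \eqn{\hat A = \tilde D^{-1/2}(A + I_N)\tilde D^{-1/2}} with
#' \eqn{\tilde D_{ii} = \sum_j (A + I_N)_{ij}}: the propagation operator of
#' the first-order graph convolution. Its spectrum lies in [-1, 1].
#'
#' @param g a \linkS4class{KnnGraph}, or a symmetric nonnegative adjacency
#'   matrix.
#' @return N x N symmetric matrix \eqn{\hat A}.
#' @export
normalizeAdjacency <- function(g) {
  a <- if (is(g, "KnnGraph")) adjacency(g) else g
  assertThat(is.matrix(a) && nrow(a) == ncol(a), "adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10)
    stop("adjacency must be symmetric", call. = FALSE)
  assertThat(all(a >= 0), "adjacency must be nonnegative")
  at <- a + diag(nrow(a))
  ds <- 1 / sqrt(rowSums(at))
  ah <- at * (ds %o% ds)
  (ah + t(ah)) / 2
}

#' Node feature matrix of a subject
#'
#' Row i of the feature matrix is node i's connectivity profile to all ROIs:
#' the input X of the graph convolution is the subject's Fisher-z matrix
#' itself (feature dimension = N, diagonal 0).
#'
#' @param conn N x N connectivity matrix.
#' @return the same N x N matrix, validated.
#' @export
nodeFeatures <- function(conn) {
  assertThat(isSymmetricTol(conn, 1e-8) && all(diag(conn) == 0),
             "connectivity must be symmetric with zero diagonal")
  conn
}
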