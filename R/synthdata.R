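## Seeded generator of multi-site case/control connectome datasets with
## ground truth: block-structured connectivity, planted group-discriminative
## edges, additive + multiplicative site effects, subject noise.

.networkNames <- c("DMN", "FPN", "CON", "SMN", "VIS", "AUD", "SAL", "SUB")

#' Configuration of the synthetic multi-site generator
#'
#' Describes the statistical structure the classifier assumes: a
#' block-structured baseline connectivity (higher correlation within
#' functional networks than between), a planted set of edges whose Fisher-z
#' value is shifted by \code{effectDelta} in patients, per-site additive
#' shifts and multiplicative scales drawn once per site (the site effect),
#' and i.i.d. symmetric subject noise. All effects act in z-space, matching
#' how group differences are tested.
#'
#' @param nRois graph size N.
#' @param nNetworks number of functional networks in the partition.
#' @param nPatients,nControls per-site counts (recycled to \code{nSites}).
#' @param nSites number of acquisition sites.
#' @param withinR,betweenR baseline Pearson correlation within / between
#'   network blocks, each in (-1, 1).
#' @param planted either a list \code{list(type = "within_network",
#'   networks = ...)}, optionally with \code{betweenPairs} (2-column matrix
#'   of network index pairs for planted between-network edges), or an
#'   explicit 2-column matrix of ROI index pairs.
#' @param effectDelta z-units added on planted edges for patients.
#' @param siteShiftSd sd of the per-site additive shift (z-units).
#' @param siteScaleSd sd of log of the per-site multiplicative scale.
#' @param subjectNoiseSd sd of the per-subject elementwise noise (z-units).
#' @param mode \code{"direct"} (draw connectivity in z-space) or
#'   \code{"timeseries"} (draw T multivariate-normal timepoints from the
#'   tanh-mapped covariance and recompute connectivity).
#' @param tPoints timepoints per subject in timeseries mode.
#' @param seed master seed of the generator.
#' @return validated list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(nRois = 60L, nNetworks = 6L, nPatients = 50L,
                            nControls = 50L, nSites = 2L, withinR = 0.3,
                            betweenR = 0.05,
                            planted = list(type = "within_network", networks = 1L),
                            effectDelta = 0.3, siteShiftSd = 0.1,
                            siteScaleSd = 0.05, subjectNoiseSd = 0.2,
                            mode = c("direct", "timeseries"), tPoints = 200L,
                            seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(nRois = as.integer(nRois), nNetworks = as.integer(nNetworks),
              nPatients = rep_len(as.integer(nPatients), nSites),
              nControls = rep_len(as.integer(nControls), nSites),
              nSites = as.integer(nSites), withinR = withinR,
              betweenR = betweenR, planted = planted,
              effectDelta = effectDelta, siteShiftSd = siteShiftSd,
              siteScaleSd = siteScaleSd, subjectNoiseSd = subjectNoiseSd,
              mode = mode, tPoints = as.integer(tPoints),
              seed = as.integer(seed))
  assertThat(abs(cfg$withinR) < 1 && abs(cfg$betweenR) < 1,
             "block correlations must lie in (-1, 1)")
  assertThat(all(c(cfg$siteShiftSd, cfg$siteScaleSd, cfg$subjectNoiseSd) >= 0),
             "noise standard deviations must be >= 0")
  assertThat(cfg$nNetworks <= cfg$nRois, "more networks than ROIs")
  class(cfg) <- "generatorConfig"
  cfg
}

#' Partition ROIs into functional networks
#'
#' Contiguous, near-equal blocks labelled with canonical network names
#' (DMN, FPN, CON, ...) cycled as needed. The first \code{nRois mod
#' nNetworks} blocks absorb the remainder.
#'
#' @param nRois,nNetworks sizes.
#' @param seed accepted for interface symmetry; the contiguous layout is
#'   deterministic.
#' @return data.frame with columns \code{roi_id}, \code{network}.
#' @export
makePartition <- function(nRois, nNetworks, seed = NULL) {
  assertThat(nNetworks <= nRois, "more networks than ROIs")
  base <- nRois %/% nNetworks
  sizes <- rep(base, nNetworks) + c(rep(1L, nRois %% nNetworks),
                                    rep(0L, nNetworks - nRois %% nNetworks))
  nm <- rep_len(.networkNames, nNetworks)
  if (anyDuplicated(nm))
    nm <- make.unique(nm, sep = "_")
  data.frame(roi_id = sprintf("ROI%03d", seq_len(nRois)),
             network = rep(nm, times = sizes), stringsAsFactors = FALSE)
}

## N x N logical mask of planted edges (symmetric, zero diagonal)
plantedMask <- function(cfg, partition) {
  n <- cfg$nRois
  mask <- matrix(FALSE, n, n)
  p <- cfg$planted
  if (is.matrix(p)) {
    for (r in seq_len(nrow(p))) mask[p[r, 1], p[r, 2]] <- mask[p[r, 2], p[r, 1]] <- TRUE
  } else {
    nets <- unique(partition$network)
    stopifnot(identical(p$type, "within_network"))
    for (k in p$networks) {
      idx <- which(partition$network == nets[k])
      mask[idx, idx] <- TRUE
    }
    if (!is.null(p$betweenPairs)) {
      bp <- matrix(as.integer(unlist(p$betweenPairs)), ncol = 2)
      for (r in seq_len(nrow(bp))) {
        ia <- which(partition$network == nets[bp[r, 1]])
        ib <- which(partition$network == nets[bp[r, 2]])
        mask[ia, ib] <- mask[ib, ia] <- TRUE
      }
    }
  }
  diag(mask) <- FALSE
  mask
}

## eigenvalue-clipped nearest-positive-definite repair
nearestPD <- function(m, floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

#' Generate a synthetic multi-site connectome dataset
#'
#' Per subject, the baseline z-connectivity is \code{atanh} of the block
#' correlation matrix; patients add \code{effectDelta} on the planted
#' edges; symmetric N(0, subjectNoiseSd) noise is added elementwise; the
#' per-site multiplicative scale and additive shift are then applied
#' (off-diagonal only). In timeseries mode each subject's z-matrix is mapped
#' back through tanh to a correlation matrix, repaired to the nearest
#' positive-definite matrix, \code{tPoints} multivariate-normal timepoints
#' are drawn, and connectivity is recomputed with
#' [fisherConnectivity()].
#'
#' @param cfg a [generatorConfig()].
#' @return list: \code{dataset} (a \linkS4class{ConnectomeExperiment}),
#'   \code{truth} (planted edge mask, per-site shift/scale draws, the
#'   partition, and the config).
#' @export
generateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "generatorConfig"))
  n <- cfg$nRois
  part <- makePartition(n, cfg$nNetworks)
  mask <- plantedMask(cfg, part)

  rBase <- matrix(cfg$betweenR, n, n)
  for (net in unique(part$network)) {
    idx <- which(part$network == net)
    rBase[idx, idx] <- cfg$withinR
  }
  z0 <- atanh(rBase)
  diag(z0) <- 0

  withSeed(deriveSeed(cfg$seed, "data"), {
    shifts <- stats::rnorm(cfg$nSites, 0, cfg$siteShiftSd)
    scales <- exp(stats::rnorm(cfg$nSites, 0, cfg$siteScaleSd))
    names(shifts) <- names(scales) <- sprintf("site%02d", seq_len(cfg$nSites))

    mats <- list(); site <- character(); label <- character()
    ut <- upper.tri(z0)
    off <- !diag(n)
    for (s in seq_len(cfg$nSites)) {
      ns <- cfg$nPatients[s] + cfg$nControls[s]
      labs <- c(rep("patient", cfg$nPatients[s]), rep("control", cfg$nControls[s]))
      for (j in seq_len(ns)) {
        e <- matrix(0, n, n)
        e[ut] <- stats::rnorm(sum(ut), 0, cfg$subjectNoiseSd)
        e <- e + t(e)
        z <- z0 + e
        if (labs[j] == "patient") z <- z + cfg$effectDelta * mask
        z <- scales[s] * z
        z[off] <- z[off] + shifts[s]
        diag(z) <- 0
        if (cfg$mode == "timeseries") {
          cmat <- tanh(z)
          diag(cmat) <- 1
          cmat <- nearestPD(cmat)
          ts <- MASS::mvrnorm(cfg$tPoints, mu = rep(0, n), Sigma = cmat)
          colnames(ts) <- part$roi_id
          z <- fisherConnectivity(ts)
        }
        mats[[length(mats) + 1L]] <- z
        site <- c(site, names(shifts)[s])
        label <- c(label, labs[j])
      }
    }
    names(mats) <- sprintf("sub%04d", seq_along(mats))
    ce <- ConnectomeExperiment(mats, site = site, label = label,
                               roiIds = part$roi_id)
    list(dataset = ce,
         truth = list(mask = mask, siteShifts = shifts, siteScales = scales,
                      partition = part, config = cfg))
  })
}

#' Named generator presets
#'
#' \describe{
#'   \item{separable}{N = 60, 6 networks, 2 sites with 50 patients + 50
#'     controls each, planted within-DMN edges, effect 0.3: comfortably
#'     learnable, the positive control.}
#'   \item{transfer_benefit}{N = 40, 5 sites with one small target site
#'     (20 + 20) and four larger source sites (40 + 40), weak effect 0.15
#'     and strong site effects: single-site training is data-starved, so
#'     pretraining on the source sites should help.}
#'   \item{null}{effect 0: no signal, the negative control for leakage.}
#'   \item{deep_vs_shallow}{planted within-network edges plus planted
#'     between-network (DMN-FPN) edges, so part of the signal lives in
#'     cross-network interactions that deeper convolution layers capture.}
#' }
#'
#' @param seed master seed stamped into every preset.
#' @return named list of [generatorConfig()] objects.
#' @export
defaultScenarios <- function(seed = 1L) {
  list(
    separable = generatorConfig(seed = seed),
    transfer_benefit = generatorConfig(
      nRois = 40L, nNetworks = 4L, nSites = 5L,
      nPatients = c(40L, 40L, 40L, 40L, 20L),
      nControls = c(40L, 40L, 40L, 40L, 20L),
      effectDelta = 0.15, siteShiftSd = 0.25, siteScaleSd = 0.1,
      seed = seed),
    null = generatorConfig(nRois = 30L, nNetworks = 3L, nSites = 2L,
                           nPatients = 25L, nControls = 25L,
                           effectDelta = 0, seed = seed),
    deep_vs_shallow = generatorConfig(
      nRois = 40L, nNetworks = 4L, nSites = 2L,
      nPatients = 40L, nControls = 40L,
      planted = list(type = "within_network", networks = 1L,
                     betweenPairs = matrix(c(1L, 2L), ncol = 2)),
      seed = seed)
  )
}
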