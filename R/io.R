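## Delimited-text interfaces: subject manifests, per-subject matrices or
## time series, ROI->network partition tables, run configuration.

#' Read a run or generator configuration (JSON or YAML)
#'
#' @param path file ending in \code{.json}, \code{.yaml} or \code{.yml}.
#' @return a named list.
#' @export
readConfig <- function(path) {
  assertThat(file.exists(path), paste("no such config file:", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname readConfig
#' @param x a named list (e.g. a [generatorConfig()] or [gcnspHyper()]).
#' @export
writeConfig <- function(x, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(x), path)
  else jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

## rebuild a generatorConfig from a deserialized list
as.generatorConfig <- function(x) {
  if (inherits(x, "generatorConfig")) return(x)
  if (is.list(x$planted) && !is.null(x$planted$betweenPairs))
    x$planted$betweenPairs <- matrix(as.integer(unlist(x$planted$betweenPairs)),
                                     ncol = 2)
  if (!is.null(x$planted) && !is.list(x$planted))
    x$planted <- matrix(as.integer(unlist(x$planted)), ncol = 2)
  keep <- intersect(names(x), names(formals(generatorConfig)))
  do.call(generatorConfig, x[keep])
}

#' Read an ROI->network partition table
#'
#' Expects columns \code{roi_id} and \code{network_name} (or
#' \code{network}).
#'
#' @param path CSV file.
#' @return data.frame \code{roi_id}, \code{network}.
#' @export
readPartition <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"network" %in% names(p) && "network_name" %in% names(p))
    p$network <- p$network_name
  assertThat(all(c("roi_id", "network") %in% names(p)),
             "partition table needs columns roi_id, network_name")
  p[, c("roi_id", "network")]
}

#' Read a subject manifest and its per-subject matrices
#'
#' The manifest is a CSV with columns \code{subject_id}, \code{site},
#' \code{label}, \code{path}. Each path points to a delimited text file:
#' either an N x N connectivity matrix, or (with \code{type =
#' "timeseries"}) a T x N time-series matrix with a header row of ROI ids,
#' which is converted through [fisherConnectivity()].
#'
#' @param path manifest CSV.
#' @param dataDir directory paths are resolved against (default: the
#'   manifest's directory).
#' @param type \code{"connectivity"} (default) or \code{"timeseries"}.
#' @return a \linkS4class{ConnectomeExperiment}.
#' @export
readManifest <- function(path, dataDir = dirname(path),
                         type = c("connectivity", "timeseries")) {
  type <- match.arg(type)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  assertThat(all(c("subject_id", "site", "label", "path") %in% names(mf)),
             "manifest needs columns subject_id, site, label, path")
  mats <- lapply(seq_len(nrow(mf)), function(i) {
    f <- file.path(dataDir, mf$path[i])
    assertThat(file.exists(f), paste("missing data file:", f))
    if (type == "timeseries") {
      ts <- as.matrix(utils::read.csv(f, check.names = FALSE))
      fisherConnectivity(ts)
    } else {
      m <- as.matrix(utils::read.table(f))
      dimnames(m) <- NULL
      symmetrizeZeroDiag(m)
    }
  })
  names(mats) <- mf$subject_id
  ConnectomeExperiment(mats, site = mf$site, label = mf$label)
}

#' Write a (synthetic) dataset to delimited files
#'
#' Emits one matrix file per subject, a manifest CSV, a partition CSV and,
#' when ground truth is given, a ground-truth JSON (planted edges, site
#' draws, config, config hash).
#'
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param dir output directory (created).
#' @param truth optional ground-truth list from [generateDataset()].
#' @return the manifest path, invisibly.
#' @export
writeDatasetFiles <- function(ce, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- subjectIds(ce)
  paths <- sprintf("%s.txt", ids)
  for (i in seq_along(ids))
    utils::write.table(connMatrix(ce, ids[i]), file.path(dir, paths[i]),
                       row.names = FALSE, col.names = FALSE)
  mf <- data.frame(subject_id = ids, site = sites(ce),
                   label = groupLabels(ce), path = paths)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(
      data.frame(roi_id = truth$partition$roi_id,
                 network_name = truth$partition$network),
      file.path(dir, "partition.csv"), row.names = FALSE)
    mask <- truth$mask
    ut <- which(upper.tri(mask) & mask, arr.ind = TRUE)
    jsonlite::write_json(
      list(planted_edges = as.data.frame(ut),
           site_shifts = as.list(truth$siteShifts),
           site_scales = as.list(truth$siteScales),
           config = unclass(truth$config),
           config_hash = configHash(truth$config),
           seed = truth$config$seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file.path(dir, "manifest.csv"))
}

#' Validate a manifest and its data files
#'
#' Checks required columns, the label vocabulary, non-empty sites, file
#' existence, square matrix shape, shape consistency across subjects, and
#' symmetry to 1e-6. Every violation is listed; an empty report means a
#' clean manifest.
#'
#' @param path manifest CSV.
#' @param dataDir directory paths are resolved against.
#' @return data.frame \code{subject}, \code{problem} (zero rows if clean).
#' @export
validateManifest <- function(path, dataDir = dirname(path)) {
  probs <- list()
  note <- function(subject, problem)
    probs[[length(probs) + 1L]] <<- data.frame(subject = subject,
                                               problem = problem)
  if (!file.exists(path)) stop("unreadable manifest: ", path, call. = FALSE)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "site", "label", "path")
  for (cl in setdiff(need, names(mf)))
    note("(manifest)", paste("missing column:", cl))
  if (length(probs) == 0) {
    bad <- !mf$label %in% c("patient", "control")
    for (s in mf$subject_id[bad])
      note(s, "label not in {patient, control}")
    for (s in mf$subject_id[!nzchar(mf$site)])
      note(s, "empty site")
    dim0 <- NA
    for (i in seq_len(nrow(mf))) {
      f <- file.path(dataDir, mf$path[i])
      if (!file.exists(f)) { note(mf$subject_id[i], "data file missing"); next }
      m <- as.matrix(utils::read.table(f))
      if (nrow(m) != ncol(m)) { note(mf$subject_id[i], "matrix not square"); next }
      if (is.na(dim0)) dim0 <- nrow(m)
      if (nrow(m) != dim0)
        note(mf$subject_id[i], sprintf("matrix is %dx%d, expected %dx%d",
                                       nrow(m), ncol(m), dim0, dim0))
      if (max(abs(m - t(m))) > 1e-6)
        note(mf$subject_id[i], "matrix asymmetric beyond 1e-6")
    }
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(subject = character(0), problem = character(0))
}
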