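## Evaluation regimes: stratified folds, multi-site pooling CV,
## leave-site-out testing, leave-site-out transfer with fine-tuning,
## RFE baselines, and metric computation.

#' Stratified k-fold split
#'
#' Folds are stratified by label within site: subjects are shuffled within
#' each site-by-label cell and dealt round-robin, so fold sizes differ by at
#' most one and each fold preserves the class ratio to within one subject.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param k number of folds (>= 2; each label class must have >= k members).
#' @param seed integer.
#' @return list of folds, each \code{list(fold, trainIds, testIds)}.
#' @export
stratifiedKFold <- function(ce, k = 10L, seed = 1L) {
  k <- as.integer(k)
  assertThat(k >= 2L, "k-fold cross-validation needs k >= 2")
  ids <- subjectIds(ce)
  lab <- groupLabels(ce)
  for (cl in unique(lab))
    if (sum(lab == cl) < k)
      stop(sprintf("class '%s' has fewer than k = %d members", cl, k),
           call. = FALSE)
  assign <- integer(0)
  names(assign) <- character(0)
  withSeed(deriveSeed(seed, "folds"), {
    ## deal each label class round-robin across folds, walking its site
    ## cells with one continuing cursor per label: every fold then holds
    ## each class to within one subject, stratified within site
    for (cl in unique(lab)) {
      cursor <- 0L
      cells <- split(ids[lab == cl], sites(ce)[lab == cl])
      for (s in cells) {
        s <- sample(s)
        f <- ((cursor + seq_along(s) - 1L) %% k) + 1L
        cursor <- cursor + length(s)
        names(f) <- s
        assign <- c(assign, f)
      }
    }
  })
  lapply(seq_len(k), function(f) {
    test <- names(assign)[assign == f]
    list(fold = f, trainIds = setdiff(ids, test), testIds = test)
  })
}

#' Classification metrics from probability scores
#'
#' Accuracy at the 0.5 threshold, sensitivity (patient recall), specificity
#' (control recall), the full ROC curve by threshold sweep, and the
#' trapezoidal AUC. With a single observed class the AUC is returned as
#' \code{NA} with a warning rather than fabricated.
#'
#' @param yTrue character labels (\code{"patient"}/\code{"control"}).
#' @param scores probabilities of the patient class.
#' @return list of class \code{"gcnspMetrics"}: \code{accuracy}, \code{auc},
#'   \code{sensitivity}, \code{specificity}, \code{roc_curve}
#'   (data.frame \code{fpr}, \code{tpr}, \code{threshold}).
#' @export
computeMetrics <- function(yTrue, scores) {
  assertThat(length(yTrue) == length(scores) && length(scores) > 0,
             "labels and scores must be equal-length and non-empty")
  pos <- yTrue == "patient"
  pred <- scores >= 0.5
  acc <- mean(pred == pos)
  sens <- if (any(pos)) mean(pred[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!pred[!pos]) else NA_real_
  if (!any(pos) || !any(!pos)) {
    warning("single-class truth: AUC undefined")
    roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1), threshold = c(Inf, -Inf))
    auc <- NA_real_
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- pos[ord]
    last <- !duplicated(s, fromLast = TRUE)  # last position of each tie group
    tpr <- cumsum(p)[last] / sum(pos)
    fpr <- cumsum(!p)[last] / sum(!pos)
    roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, s[last]))
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  }
  out <- list(accuracy = acc, auc = auc, sensitivity = sens,
              specificity = spec, roc_curve = roc)
  class(out) <- "gcnspMetrics"
  out
}

## upper-triangle feature matrix: subjects x d (d = N(N-1)/2)
featureMatrix <- function(ce, ids = subjectIds(ce)) {
  n <- nRois(ce)
  ut <- which(upper.tri(matrix(0, n, n)))
  t(SummarizedExperiment::assay(ce, "z")[ut, ids, drop = FALSE])
}

## vectorized two-sample pooled-variance t statistics per column
colTstats <- function(x, isGroup1) {
  n1 <- sum(isGroup1); n2 <- sum(!isGroup1)
  x1 <- x[isGroup1, , drop = FALSE]; x2 <- x[!isGroup1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2); v2 <- colSums(sweep(x2, 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0  # zero pooled variance: no evidence, least important
  t
}

#' Recursive feature elimination ranked by two-sample t-score
#'
#' Iteratively drops the 10% of surviving features with the lowest absolute
#' two-sample t statistic (at least one per round), recomputing t on the
#' survivors, until \code{max(1, ceiling(ratio * d))} features remain. Ties
#' are broken deterministically: among equal |t|, the higher column index is
#' dropped first. Zero-variance features get |t| = 0 (least important).
#'
#' @param x n x d feature matrix.
#' @param y labels (\code{"patient"}/\code{"control"}).
#' @param ratio retained fraction of the original dimension (default 1e-4).
#' @param step fraction of survivors dropped per round (default 0.1).
#' @return list: \code{selected} (retained column indices, by decreasing
#'   final importance), \code{ranking} (length-d integer, 1 = most
#'   important), \code{nSelected}.
#' @export
rfeRankT <- function(x, y, ratio = 1e-4, step = 0.1) {
  d <- ncol(x)
  assertThat(d >= 1, "no features")
  isP <- y == "patient"
  assertThat(any(isP) && any(!isP), "both classes must be present")
  target <- max(1L, as.integer(ceiling(ratio * d)))
  surviving <- seq_len(d)
  rank <- integer(d)
  nextWorst <- d
  repeat {
    tv <- abs(colTstats(x[, surviving, drop = FALSE], isP))
    if (length(surviving) <= target) break
    nDrop <- min(max(1L, as.integer(floor(step * length(surviving)))),
                 length(surviving) - target)
    ## ascending |t|; ties: higher original index dropped first
    ord <- order(tv, -surviving)
    drop <- ord[seq_len(nDrop)]
    ## worst of this round gets the worst remaining rank
    rank[surviving[drop]] <- nextWorst - seq_len(nDrop) + 1L
    nextWorst <- nextWorst - nDrop
    surviving <- surviving[-drop]
  }
  ## survivors ranked by final |t| descending, ties toward lower index
  ordFinal <- order(-tv, surviving)
  rank[surviving[ordFinal]] <- seq_along(surviving)
  list(selected = surviving[ordFinal], ranking = rank,
       nSelected = length(surviving))
}

## fit one linear classifier on selected, standardized features
fitBaseline <- function(xTrain, yTrain, clf) {
  yF <- factor(yTrain, levels = c("control", "patient"))
  switch(clf,
    svm = e1071::svm(xTrain, yF, kernel = "linear", cost = 1,
                     probability = TRUE, scale = FALSE),
    lda = MASS::lda(xTrain, grouping = yF),
    lr  = suppressWarnings(stats::glm.fit(cbind(1, xTrain),
                                          as.integer(yF == "patient"),
                                          family = stats::binomial())),
    stop("unknown classifier: ", clf))
}

predictBaseline <- function(fit, xTest, clf) {
  switch(clf,
    svm = {
      pr <- attr(stats::predict(fit, xTest, probability = TRUE), "probabilities")
      pr[, "patient"]
    },
    lda = stats::predict(fit, xTest)$posterior[, "patient"],
    lr  = as.vector(stats::plogis(cbind(1, xTest) %*% fit$coefficients)))
}

#' RFE + linear-classifier baselines under given folds
#'
#' Per fold: site regression, recursive feature elimination and feature
#' standardization are all fitted on the training fold only; a linear
#' classifier (linear-kernel SVM with unit cost, LDA, or logistic
#' regression) is fitted on the selected features and scored on the test
#' fold; metrics are computed on the pooled out-of-fold scores.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param clf \code{"svm"}, \code{"lda"} or \code{"lr"}.
#' @param folds a fold list from [stratifiedKFold()].
#' @param rfeRatio retained feature fraction (default 1e-4).
#' @param regressSite fit-and-apply site regression inside each fold.
#' @return list: \code{metrics}, \code{scores} (per-subject out-of-fold),
#'   \code{provenance} (per-fold fitted-object audit trail).
#' @export
baselineClassify <- function(ce, clf = c("svm", "lda", "lr"), folds,
                             rfeRatio = 1e-4, regressSite = TRUE) {
  clf <- match.arg(clf)
  lab <- groupLabels(ce); names(lab) <- subjectIds(ce)
  scores <- numeric(0)
  prov <- list()
  for (fd in folds) {
    dsF <- if (regressSite) regressOutSite(ce, fd$trainIds) else ce
    xTr <- featureMatrix(dsF, fd$trainIds)
    xTe <- featureMatrix(dsF, fd$testIds)
    sel <- rfeRankT(xTr, lab[fd$trainIds], ratio = rfeRatio)$selected
    mu <- colMeans(xTr[, sel, drop = FALSE])
    sd0 <- apply(xTr[, sel, drop = FALSE], 2, stats::sd)
    sd0[sd0 == 0] <- 1
    std <- function(x) sweep(sweep(x[, sel, drop = FALSE], 2, mu), 2, sd0, "/")
    fit <- fitBaseline(std(xTr), lab[fd$trainIds], clf)
    sc <- predictBaseline(fit, std(xTe), clf)
    names(sc) <- fd$testIds
    scores <- c(scores, sc)
    prov[[fd$fold]] <- list(fitIds = fd$trainIds, testIds = fd$testIds,
                            selected = sel)
  }
  scores <- scores[subjectIds(ce)[subjectIds(ce) %in% names(scores)]]
  list(metrics = computeMetrics(lab[names(scores)], scores),
       scores = data.frame(subject_id = names(scores), score = scores,
                           label = lab[names(scores)], row.names = NULL),
       provenance = prov)
}

## shared per-fold graph-model fit: harmonize, build graph, train, score test
fitFoldGcnsp <- function(ce, fd, hyper, model, seed, regressSite = TRUE) {
  dsF <- if (regressSite) regressOutSite(ce, fd$trainIds) else ce
  mc <- meanConnectivity(dsF, fd$trainIds)
  g <- buildKnnGraph(mc, k = hyper$knn)
  ah <- normalizeAdjacency(g)
  fit <- trainGcnsp(dsF[, fd$trainIds], ah, hyper, model = model,
                    seed = deriveSeed(seed, sprintf("fold%02d", fd$fold)))
  sc <- predictGcnsp(fit, dsF, fd$testIds)
  list(fit = fit, scores = sc,
       provenance = list(fitIds = fd$trainIds, testIds = fd$testIds))
}

#' Multi-site pooling cross-validation
#'
#' k-fold cross-validation on the pooled multi-site dataset. Within each
#' fold, site regression, the mean-connectivity K-NN graph and the model are
#' all fitted on the training fold only; metrics are computed on the pooled
#' out-of-fold predictions.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}.
#' @param hyper a [gcnspHyper()] list.
#' @param model one of \code{"gcnsp"}, \code{"gcn"}, \code{"rfe_svm"},
#'   \code{"rfe_lda"}, \code{"rfe_lr"}.
#' @param k number of folds (default 10).
#' @param seed integer.
#' @param rfeRatio retained feature fraction for the RFE baselines.
#' @param regressSite fit-and-apply site regression inside each fold.
#' @return list: \code{metrics}, \code{scores}, \code{provenance},
#'   \code{model}.
#' @export
multiSitePoolingCV <- function(ce, hyper = gcnspHyper(),
                               model = c("gcnsp", "gcn", "rfe_svm",
                                         "rfe_lda", "rfe_lr"),
                               k = 10L, seed = hyper$seed, rfeRatio = 1e-4,
                               regressSite = TRUE) {
  model <- match.arg(model)
  folds <- stratifiedKFold(ce, k = k, seed = seed)
  if (startsWith(model, "rfe_")) {
    out <- baselineClassify(ce, sub("^rfe_", "", model), folds,
                            rfeRatio = rfeRatio, regressSite = regressSite)
    out$model <- model
    return(out)
  }
  lab <- groupLabels(ce); names(lab) <- subjectIds(ce)
  scoreRows <- list(); prov <- list()
  for (fd in folds) {
    r <- fitFoldGcnsp(ce, fd, hyper, model, seed, regressSite)
    r$scores$fold <- fd$fold
    scoreRows[[fd$fold]] <- r$scores
    prov[[fd$fold]] <- r$provenance
  }
  sc <- do.call(rbind, scoreRows)
  sc <- sc[match(subjectIds(ce), sc$subject_id), ]
  list(metrics = computeMetrics(sc$label, sc$score), scores = sc,
       provenance = prov, model = model)
}

#' Leave-site-out test classification
#'
#' For each site in turn: the model (including site regression, the
#' population graph and all parameters) is fitted on the remaining sites
#' with no exposure to the held-out site, then scored on the held-out site.
#' The held-out site's data pass through un-harmonized, since its site
#' effect cannot be estimated without touching it.
#'
#' @inheritParams multiSitePoolingCV
#' @return named list (one entry per site): \code{metrics}, \code{scores},
#'   \code{provenance}.
#' @export
leaveSiteOutTest <- function(ce, hyper = gcnspHyper(), model = c("gcnsp", "gcn"),
                             seed = hyper$seed) {
  model <- match.arg(model)
  siteLevels <- unique(sites(ce))
  assertThat(length(siteLevels) >= 2, "leave-site-out needs at least two sites")
  lab <- groupLabels(ce); names(lab) <- subjectIds(ce)
  out <- list()
  for (s in siteLevels) {
    testIds <- subjectIds(ce)[sites(ce) == s]
    trainIds <- setdiff(subjectIds(ce), testIds)
    ## a single remaining training site has no estimable between-site
    ## effect: harmonization degrades to the identity
    ceTrain <- if (length(setdiff(siteLevels, s)) >= 2)
      regressOutSite(ce[, trainIds], trainIds) else ce[, trainIds]
    mc <- meanConnectivity(ceTrain, trainIds)
    ah <- normalizeAdjacency(buildKnnGraph(mc, k = hyper$knn))
    fit <- trainGcnsp(ceTrain, ah, hyper, model = model,
                      seed = deriveSeed(seed, paste0("site_", s)))
    sc <- predictGcnsp(fit, ce, testIds)
    out[[s]] <- list(metrics = computeMetrics(sc$label, sc$score), scores = sc,
                     provenance = list(fitIds = trainIds, testIds = testIds))
  }
  out
}

#' Pre-train a GCNSP model on source sites
#'
#' Trains on the source dataset only (no target data enters the fit); an
#' internal stratified 10% holdout of the source is scored for logging. The
#' returned model can be serialized with [saveCheckpoint()] and reused as
#' the warm start of [transferCV()].
#'
#' @param ce the source \linkS4class{ConnectomeExperiment}.
#' @param hyper a [gcnspHyper()] list.
#' @param seed integer.
#' @param regressSite harmonize the source sites before training (needs
#'   >= 2 source sites).
#' @return list: \code{model} (a \linkS4class{GcnspModel}),
#'   \code{sourceAccuracy} (holdout accuracy, logging only).
#' @export
pretrainGcnsp <- function(ce, hyper = gcnspHyper(), seed = hyper$seed,
                          regressSite = length(unique(sites(ce))) >= 2) {
  holdFold <- stratifiedKFold(ce, k = 10L, seed = deriveSeed(seed, "holdout"))[[1]]
  trainIds <- holdFold$trainIds
  dsF <- if (regressSite) regressOutSite(ce, trainIds) else ce
  mc <- meanConnectivity(dsF, trainIds)
  ah <- normalizeAdjacency(buildKnnGraph(mc, k = hyper$knn))
  fit <- trainGcnsp(dsF[, trainIds], ah, hyper, model = "gcnsp",
                    seed = deriveSeed(seed, "pretrain"))
  sc <- predictGcnsp(fit, dsF, holdFold$testIds)
  list(model = fit, sourceAccuracy = mean((sc$score >= 0.5) ==
                                            (sc$label == "patient")))
}

#' Select the epoch with the best validation accuracy
#'
#' @param history a training-history data.frame with a \code{val_acc}
#'   column, or a numeric vector of per-epoch validation accuracies.
#' @return the argmax epoch; ties resolve to the earliest.
#' @export
optimalEpoch <- function(history) {
  va <- if (is.data.frame(history)) history$val_acc else as.numeric(history)
  assertThat(length(va) > 0 && !all(is.na(va)),
             "history holds no validation accuracy")
  which.max(va)
}

## mean over folds of scalar metrics (AUC may be NA in degenerate folds)
meanMetrics <- function(ms) {
  g <- function(f) mean(vapply(ms, function(m) m[[f]], 0), na.rm = TRUE)
  list(accuracy = g("accuracy"), auc = g("auc"),
       sensitivity = g("sensitivity"), specificity = g("specificity"))
}

#' Leave-site-out transfer learning with fine-tuning
#'
#' 10-fold cross-validation within the target site. Each fold initializes
#' from the pretrained source model (all parameters are updated during
#' fine-tuning), fine-tunes on the 90% training portion with batch size 16,
#' and tests on the held-out 10%. A stratified 1/9 of the training portion
#' is carved out as a validation set; fixed-epoch metrics use the final
#' epoch, optimal-epoch metrics re-evaluate the parameter snapshot from the
#' epoch with the highest validation accuracy. Metrics are averaged over
#' folds. With \code{pretrained = NULL} the same protocol runs from a fresh
#' initialisation: the non-transfer comparator.
#'
#' @param ce a \linkS4class{ConnectomeExperiment} containing the target site.
#' @param targetSite site identifier.
#' @param hyper a [gcnspHyper()] list (epochs here = fine-tuning epochs).
#' @param pretrained result of [pretrainGcnsp()], a
#'   \linkS4class{GcnspModel}, or \code{NULL} for the non-transfer arm.
#' @param seed integer.
#' @param minGroup site-inclusion rule: the larger diagnostic group must
#'   have at least this many subjects (default 20; 0 disables).
#' @param fineTuneBatch minibatch size during fine-tuning (default 16).
#' @return list: \code{site}, \code{metricsFixed}, \code{metricsOptimal},
#'   \code{chosenEpochs}, \code{foldMetrics}, \code{history} (per-fold
#'   fine-tuning histories).
#' @export
transferCV <- function(ce, targetSite, hyper = gcnspHyper(), pretrained = NULL,
                       seed = hyper$seed, minGroup = 20L, fineTuneBatch = 16L) {
  assertThat(targetSite %in% sites(ce),
             sprintf("site '%s' absent from the dataset", targetSite))
  target <- ce[, sites(ce) == targetSite]
  tab <- table(factor(groupLabels(target), levels = c("patient", "control")))
  if (minGroup > 0 && max(tab) < minGroup)
    stop(sprintf("target site '%s' fails the inclusion rule (largest group %d < %d)",
                 targetSite, max(tab), minGroup), call. = FALSE)
  if (!is.null(pretrained) && !is(pretrained, "GcnspModel"))
    pretrained <- pretrained$model

  hyperFT <- hyper
  hyperFT$batchSize <- as.integer(fineTuneBatch)
  folds <- stratifiedKFold(target, k = 10L, seed = seed)
  lab <- groupLabels(target); names(lab) <- subjectIds(target)

  foldMetricsFixed <- list(); foldMetricsOpt <- list()
  chosen <- integer(0); histories <- list()
  for (fd in folds) {
    sub90 <- target[, fd$trainIds]
    valIds <- stratifiedKFold(sub90, k = 9L,
                              seed = deriveSeed(seed, sprintf("val%02d", fd$fold)))[[1]]$testIds
    ah <- if (!is.null(pretrained)) pretrained@aHat else {
      mc <- meanConnectivity(target, setdiff(fd$trainIds, valIds))
      normalizeAdjacency(buildKnnGraph(mc, k = hyper$knn))
    }
    snaps <- vector("list", hyperFT$epochs)
    cb <- function(epoch, params, row) snaps[[epoch]] <<- params
    fit <- trainGcnsp(sub90, ah, hyperFT,
                      validationIds = valIds,
                      initParams = if (!is.null(pretrained)) modelParams(pretrained),
                      callback = cb,
                      seed = deriveSeed(seed, sprintf("ft%02d", fd$fold)))
    histories[[fd$fold]] <- trainingHistory(fit)
    scF <- predictGcnsp(fit, target, fd$testIds)
    foldMetricsFixed[[fd$fold]] <- computeMetrics(scF$label, scF$score)
    if (hyperFT$epochs == 0L) {
      ## no fine-tuning: the pretrained (or fresh) model is the final model
      chosen <- c(chosen, 0L)
      foldMetricsOpt[[fd$fold]] <- foldMetricsFixed[[fd$fold]]
    } else {
      eStar <- optimalEpoch(trainingHistory(fit))
      chosen <- c(chosen, eStar)
      optModel <- new("GcnspModel", params = snaps[[eStar]], aHat = ah,
                      hyper = fit@hyper, history = fit@history,
                      fitIds = fit@fitIds)
      scO <- predictGcnsp(optModel, target, fd$testIds)
      foldMetricsOpt[[fd$fold]] <- computeMetrics(scO$label, scO$score)
    }
  }
  list(site = targetSite,
       metricsFixed = meanMetrics(foldMetricsFixed),
       metricsOptimal = meanMetrics(foldMetricsOpt),
       chosenEpochs = chosen,
       foldMetrics = list(fixed = foldMetricsFixed, optimal = foldMetricsOpt),
       history = histories)
}
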