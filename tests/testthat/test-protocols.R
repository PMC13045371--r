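test_that("stratified folds preserve class ratio and cover the population", {
  ce <- toyCE(20, n = 5, nSites = 2,
              labels = rep(c("patient", "control"), each = 10))
  folds <- stratifiedKFold(ce, k = 10, seed = 1)
  for (fd in folds) {
    expect_length(fd$testIds, 2)
    expect_setequal(groupLabels(ce)[match(fd$testIds, subjectIds(ce))],
                    c("patient", "control"))
    expect_length(intersect(fd$trainIds, fd$testIds), 0)
    expect_setequal(c(fd$trainIds, fd$testIds), subjectIds(ce))
  }
  expect_setequal(unlist(lapply(folds, `[[`, "testIds")), subjectIds(ce))
  expect_identical(stratifiedKFold(ce, 10, seed = 1),
                   stratifiedKFold(ce, 10, seed = 1))
  expect_error(stratifiedKFold(ce, k = 1), "k >= 2")
  expect_error(stratifiedKFold(ce, k = 11), "fewer than k")
})

test_that("computeMetrics matches hand-worked values and conventions", {
  y <- c("patient", "patient", "control", "patient", "control", "control")
  s <- c(0.9, 0.6, 0.55, 0.4, 0.3, 0.1)
  m <- computeMetrics(y, s)
  expect_equal(m$accuracy, 4 / 6)       # one miss in each class at 0.5
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  # AUC oracle: pairwise concordance (Mann-Whitney), ties counted 1/2
  conc <- function(y, s) {
    ps <- s[y == "patient"]; cs <- s[y == "control"]
    g <- outer(ps, cs, ">"); t <- outer(ps, cs, "==")
    mean(g + 0.5 * t)
  }
  expect_equal(m$auc, conc(y, s), tolerance = 1e-12)
  # perfect separation
  mp <- computeMetrics(c("patient", "control"), c(0.9, 0.1))
  expect_equal(unlist(mp[c("accuracy", "auc", "sensitivity", "specificity")]),
               c(accuracy = 1, auc = 1, sensitivity = 1, specificity = 1))
  # constant scores: AUC 0.5 by the tie convention
  expect_equal(computeMetrics(y, rep(0.5, 6))$auc, 0.5)
  # ROC is monotone and its trapezoid equals the reported AUC
  expect_true(all(diff(m$roc_curve$fpr) >= 0))
  expect_true(all(diff(m$roc_curve$tpr) >= 0))
  tz <- sum(diff(m$roc_curve$fpr) *
              (head(m$roc_curve$tpr, -1) + tail(m$roc_curve$tpr, -1)) / 2)
  expect_equal(m$auc, tz, tolerance = 1e-8)
  # degenerate truth is flagged, not fabricated
  expect_warning(ms <- computeMetrics(rep("patient", 3), c(0.2, 0.6, 0.9)),
                 "single-class")
  expect_true(is.na(ms$auc))
})

test_that("computeMetrics AUC agrees with pROC on random vectors", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(6:40, 1))
    y <- withr::with_seed(s + 100, sample(c("patient", "control"), n,
                                          replace = TRUE, prob = c(.5, .5)))
    if (length(unique(y)) < 2) next
    sc <- withr::with_seed(s + 200, round(runif(n), 2))  # include ties
    ours <- computeMetrics(y, sc)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = y, predictor = sc, levels = c("control", "patient"),
      direction = "<")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("RFE retains the contracted feature count and planted survivors", {
  set.seed(21)
  y <- rep(c("patient", "control"), each = 10)
  x <- matrix(rnorm(20 * 400), 20)
  x[y == "patient", 123] <- x[y == "patient", 123] + 5  # huge planted effect
  r <- rfeRankT(x, y, ratio = 1e-4)
  expect_equal(r$nSelected, max(1, ceiling(1e-4 * 400)))
  expect_true(123 %in% r$selected)
  expect_equal(r$ranking[123], 1L)

  # ranking is a permutation of 1..d
  expect_setequal(r$ranking, seq_len(400))

  # retained-count arithmetic at several dimensions
  x2 <- matrix(rnorm(20 * 100), 20)
  expect_equal(rfeRankT(x2, y, ratio = 1e-4)$nSelected, 1L)
  expect_equal(rfeRankT(x2, y, ratio = 0.05)$nSelected, 5L)

  # zero-variance features are least important
  x3 <- cbind(x2[, 1:10], const = 0)
  r3 <- rfeRankT(x3, y, ratio = 0.5)
  expect_false(11 %in% r3$selected)

  # equal-mean features: the result is deterministic and reproducible
  x4 <- matrix(rep(rnorm(20), 6), 20)
  r4a <- rfeRankT(x4, y, ratio = 0.3)
  r4b <- rfeRankT(x4, y, ratio = 0.3)
  expect_identical(r4a, r4b)
})

test_that("RFE selection is invariant to column permutation up to ties", {
  set.seed(8)
  y <- rep(c("patient", "control"), each = 8)
  x <- matrix(rnorm(16 * 60), 16)
  p <- sample(60)
  sel1 <- sort(rfeRankT(x, y, ratio = 0.1)$selected)
  sel2 <- sort(p[rfeRankT(x[, p], y, ratio = 0.1)$selected])
  expect_identical(sel1, sel2)
})

test_that("pooling CV fits every object inside the training fold only", {
  fx <- smallSeparable()
  hy <- gcnspHyper(hiddenSize = 8L, epochs = 15L, batchSize = 16L)
  res <- multiSitePoolingCV(fx$gen$dataset, hy, model = "gcnsp", k = 5,
                            seed = 2)
  for (pr in res$provenance) {
    expect_length(intersect(pr$fitIds, pr$testIds), 0)
    expect_setequal(c(pr$fitIds, pr$testIds), subjectIds(fx$gen$dataset))
  }
  # every subject scored exactly once out-of-fold
  expect_setequal(res$scores$subject_id, subjectIds(fx$gen$dataset))
  expect_true(all(res$scores$score >= 0 & res$scores$score <= 1))

  # the plain-GCN ablation runs under the same protocol
  resG <- multiSitePoolingCV(fx$gen$dataset, hy, model = "gcn", k = 5,
                             seed = 2)
  expect_true(is.finite(resG$metrics$accuracy))
})

test_that("RFE baselines separate the calibrated synthetic task", {
  gen <- generateDataset(generatorConfig(nRois = 20L, nNetworks = 2L,
                                         nSites = 2L, nPatients = 20L,
                                         nControls = 20L, effectDelta = 0.4,
                                         seed = 17L))
  folds <- stratifiedKFold(gen$dataset, k = 5, seed = 3)
  for (clf in c("svm", "lda", "lr")) {
    res <- baselineClassify(gen$dataset, clf, folds, rfeRatio = 0.2)
    expect_gte(res$metrics$accuracy, 0.9)
    for (pr in res$provenance)
      expect_length(intersect(pr$fitIds, pr$testIds), 0)
  }
})

test_that("feature selection is isolated from test-fold labels", {
  fx <- smallSeparable()
  ce <- fx$gen$dataset
  folds <- stratifiedKFold(ce, k = 4, seed = 9)
  res1 <- baselineClassify(ce, "lda", folds, rfeRatio = 0.1)
  # flip every test-fold label: training-side selections must not move
  ceFlip <- ce
  fd <- folds[[1]]
  flipPos <- match(fd$testIds, subjectIds(ce))
  SummarizedExperiment::colData(ceFlip)$label[flipPos] <-
    ifelse(groupLabels(ce)[flipPos] == "patient", "control", "patient")
  res2 <- baselineClassify(ceFlip, "lda", folds, rfeRatio = 0.1)
  expect_identical(res1$provenance[[1]]$selected,
                   res2$provenance[[1]]$selected)
  expect_equal(res1$scores$score[match(fd$testIds, res1$scores$subject_id)],
               res2$scores$score[match(fd$testIds, res2$scores$subject_id)])
})

test_that("leave-site-out never touches the held-out site", {
  gen <- generateDataset(generatorConfig(nRois = 15L, nNetworks = 3L,
                                         nSites = 3L, nPatients = 8L,
                                         nControls = 8L, seed = 23L))
  hy <- gcnspHyper(hiddenSize = 8L, epochs = 10L, batchSize = 16L)
  res <- leaveSiteOutTest(gen$dataset, hy, seed = 4)
  expect_setequal(names(res), unique(sites(gen$dataset)))
  for (s in names(res)) {
    pr <- res[[s]]$provenance
    heldOut <- subjectIds(gen$dataset)[sites(gen$dataset) == s]
    expect_setequal(pr$testIds, heldOut)
    expect_length(intersect(pr$fitIds, heldOut), 0)
  }
  ceOne <- gen$dataset[, sites(gen$dataset) == "site01"]
  expect_error(leaveSiteOutTest(ceOne, hy), "at least two sites")
})

test_that("optimal epoch selection takes the earliest argmax", {
  expect_equal(optimalEpoch(c(0.5, 0.8, 0.6)), 2L)
  expect_equal(optimalEpoch(c(0.1, 0.2, 0.9, 0.5, 0.3, 0.6, 0.9)), 3L)
  expect_equal(optimalEpoch(seq(0.1, 0.9, length.out = 5)), 5L)
  expect_error(optimalEpoch(numeric(0)), "no validation")
})

test_that("transfer with zero fine-tuning equals pretrained evaluation", {
  gen <- generateDataset(generatorConfig(nRois = 15L, nNetworks = 3L,
                                         nSites = 3L, nPatients = 10L,
                                         nControls = 10L, seed = 31L))
  ce <- gen$dataset
  hy <- gcnspHyper(hiddenSize = 8L, epochs = 12L, batchSize = 16L)
  src <- ce[, sites(ce) != "site03"]
  pre <- pretrainGcnsp(src, hy, seed = 11)
  expect_true(is.finite(pre$sourceAccuracy))
  # pretraining provenance excludes all target-site subjects
  target <- subjectIds(ce)[sites(ce) == "site03"]
  expect_length(intersect(pre$model@fitIds, target), 0)

  hy0 <- hy; hy0$epochs <- 0L
  tr0 <- transferCV(ce, "site03", hy0, pretrained = pre, seed = 7,
                    minGroup = 0)
  direct <- predictGcnsp(pre$model, ce, target)
  pooledAcc <- mean((direct$score >= 0.5) == (direct$label == "patient"))
  # equal fold sizes: fold-mean accuracy equals pooled accuracy
  expect_equal(tr0$metricsFixed$accuracy, pooledAcc, tolerance = 1e-8)
  expect_equal(tr0$metricsOptimal$accuracy, tr0$metricsFixed$accuracy)
})

test_that("transfer enforces inclusion and site-existence rules", {
  fx <- smallSeparable()
  hy <- gcnspHyper(hiddenSize = 8L, epochs = 2L)
  expect_error(transferCV(fx$gen$dataset, "nowhere", hy), "absent")
  expect_error(transferCV(fx$gen$dataset, "site01", hy, minGroup = 20),
               "inclusion")
})

test_that("fine-tuning from a checkpoint runs end to end", {
  gen <- generateDataset(generatorConfig(nRois = 15L, nNetworks = 3L,
                                         nSites = 2L, nPatients = 15L,
                                         nControls = 15L, effectDelta = 0.4,
                                         seed = 41L))
  ce <- gen$dataset
  hy <- gcnspHyper(hiddenSize = 8L, epochs = 8L, batchSize = 16L)
  src <- ce[, sites(ce) == "site01"]
  pre <- pretrainGcnsp(src, hy, seed = 2, regressSite = FALSE)
  tr <- transferCV(ce, "site02", hy, pretrained = pre, seed = 3, minGroup = 0)
  expect_true(all(tr$chosenEpochs >= 1 & tr$chosenEpochs <= 8))
  expect_length(tr$history, 10)
  expect_true(is.finite(tr$metricsFixed$accuracy))
  expect_true(is.finite(tr$metricsOptimal$accuracy))
})
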