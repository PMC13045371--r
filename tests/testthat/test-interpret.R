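test_that("feature maps average layer activations over subjects", {
  sm <- smallModel()
  ce <- sm$fx$ce
  one <- subjectIds(ce)[1]
  fm1 <- extractFeatureMaps(sm$fit, ce, one, layer = "gcn2")
  fw <- gcnspForward(sm$fit@aHat, connMatrix(ce, one), modelParams(sm$fit))
  expect_equal(fm1$maps, fw$z)
  expect_equal(fm1$subjectCount, 1L)

  # averaging commutes with channel selection (linearity)
  ids <- subjectIds(ce)[1:4]
  fmA <- extractFeatureMaps(sm$fit, ce, ids, layer = "gcn1")
  perSubj <- lapply(ids, function(id)
    gcnspForward(sm$fit@aHat, connMatrix(ce, id), modelParams(sm$fit))$h1[, 3])
  expect_equal(fmA$maps[, 3], Reduce(`+`, perSubj) / 4)
  expect_error(extractFeatureMaps(sm$fit, ce, character(0)), "empty")
})

test_that("network association identifies planted single-network channels", {
  part <- makePartition(20, 4)
  # channel k activates exclusively inside network (k mod 4) + 1
  set.seed(10)
  nets <- unique(part$network)
  maps <- sapply(1:8, function(ch) {
    v <- runif(20, 0, 0.1)
    v[part$network == nets[(ch - 1) %% 4 + 1]] <- 1 + runif(5)
    v
  })
  ov <- networkOverlap(maps, part, topFraction = 0.25)
  expect_equal(sum(ov$pctChannelsRaw), 100)
  expect_equal(sum(ov$pctChannelsCorrected), 100)
  expect_equal(ov$pctChannelsCorrected, rep(25, 4))  # 2 channels per network
  expect_error(networkOverlap(maps, part, topFraction = 0), "topFraction")
  expect_error(networkOverlap(maps, part, topFraction = 1.2), "topFraction")
})

test_that("embedding CAM conserves the class score exactly", {
  sm <- smallModel()
  p <- modelParams(sm$fit)
  ce <- sm$fx$ce
  for (id in subjectIds(ce)[1:10]) {
    fw <- gcnspForward(sm$fit@aHat, connMatrix(ce, id), p)
    for (cl in c("patient", "control")) {
      cam <- camEmbedding(p, fw, classId = cl)
      expect_equal(sum(cam$embeddingScores), cam$classScore, tolerance = 1e-8)
      expect_equal(cam$classScore, unname(fw$logits[cl]))
    }
    # two-class pattern: M_patient + M_control = (w_p + w_c) * z_g
    cp <- camEmbedding(p, fw, "patient")$embeddingScores
    cc <- camEmbedding(p, fw, "control")$embeddingScores
    expect_equal(cp + cc, (p$dense_w[, 1] + p$dense_w[, 2]) * fw$zg)
  }
  # zero embedding: all scores zero
  fw0 <- gcnspForward(sm$fit@aHat, matrix(0, 20, 20), p)
  cam0 <- camEmbedding(p, fw0)
  expect_equal(sum(abs(cam0$embeddingScores)), 0)
  expect_equal(cam0$classScore, 0)
  # a biased head would break the identity and must be refused
  pb <- p; pb$dense_b <- c(0.1, -0.1)
  expect_error(camEmbedding(pb, fw0), "bias")
})

test_that("node CAM backprojects through the pooling chain", {
  d2 <- 3
  z <- matrix(rnorm(15), 5, d2)
  # selector pooling: layer 1 keeps nodes 2 and 4
  th1 <- rbind(c(0, 1, 0, 0, 0), c(0, 0, 0, 1, 0))
  th2 <- matrix(c(1, 1), 1, 2)
  denseW <- matrix(rnorm((2 + 1) * d2 * 2), ncol = 2)
  p <- list(w0 = diag(5), w1 = diag(d2), theta = list(th1, th2),
            dense_w = denseW)
  emb <- hierarchicalEmbedding(z, p$theta)
  fw <- list(zg = emb$zg, zgLayers = emb$zgLayers, z = z,
             logits = c(patient = sum(emb$zg * denseW[, 1]),
                        control = sum(emb$zg * denseW[, 2])))
  cam <- camEmbedding(p, fw)
  ns <- camNodes(cam, p$theta)
  expect_equal(ns[c(1, 3, 5)], rep(0, 3))  # only selected nodes score

  # independent chain oracle by explicit summation
  oracle <- numeric(5)
  proj1 <- t(th1); proj2 <- t(th1) %*% t(th2)
  for (n in 1:5) for (ch in 1:d2) {
    for (i in 1:2) oracle[n] <- oracle[n] + proj1[n, i] * cam$layerScores[[1]][i, ch]
    oracle[n] <- oracle[n] + proj2[n, 1] * cam$layerScores[[2]][1, ch]
  }
  expect_equal(ns, oracle, tolerance = 1e-12)

  # identity pooling: node scores equal channel-summed embedding scores
  pI <- list(w0 = diag(5), w1 = diag(d2), theta = list(diag(5)),
             dense_w = matrix(rnorm(5 * d2 * 2), ncol = 2))
  embI <- hierarchicalEmbedding(z, pI$theta)
  fwI <- list(zg = embI$zg, zgLayers = embI$zgLayers, z = z,
              logits = c(patient = sum(embI$zg * pI$dense_w[, 1]), control = 0))
  camI <- camEmbedding(pI, fwI)
  expect_equal(camNodes(camI, pI$theta), rowSums(camI$layerScores[[1]]))
})

test_that("edge CAM is exact for a linear-regime network", {
  # all-positive weights and features keep every ReLU in its linear branch,
  # where gradient x input must sum exactly to the class score
  n <- 6
  hy <- gcnspHyper(hiddenSize = 4L, poolRatio = 0.5, nPoolLayers = 2L)
  p <- gcnspInit(n, hy, seed = 5)
  p$w0 <- abs(p$w0); p$w1 <- abs(p$w1)
  p$theta <- lapply(p$theta, abs)
  x <- abs(randSym(n, seed = 6)) + 0.5; diag(x) <- 0
  ah <- normalizeAdjacency(abs(randSym(n, seed = 7)))
  fw <- gcnspForward(ah, x, p)
  expect_true(all(fw$pre1 > 0) && all(fw$pre2 > 0))  # confirmed linear regime
  es <- camEdges(p, x, classId = "patient", aHat = ah)
  expect_equal(sum(es), unname(fw$logits["patient"]), tolerance = 1e-8)
  expect_equal(es, t(es))
  expect_equal(diag(es), rep(0, n))
  # zero input gives a zero map
  expect_equal(camEdges(p, matrix(0, n, n), aHat = ah), matrix(0, n, n))
})

test_that("edge CAM matches a finite-difference gradient oracle", {
  sm <- smallModel()
  p <- modelParams(sm$fit)
  x <- connMatrix(sm$fx$ce, 3)
  ah <- sm$fit@aHat
  es <- camEdges(p, x, aHat = ah)
  eps <- 1e-6
  for (idx in list(c(2, 5), c(1, 9), c(7, 12))) {
    i <- idx[1]; j <- idx[2]
    xp <- x; xp[i, j] <- xp[i, j] + eps; xp[j, i] <- xp[j, i] + eps
    xm <- x; xm[i, j] <- xm[i, j] - eps; xm[j, i] <- xm[j, i] - eps
    gNum <- (gcnspForward(ah, xp, p)$logits[1] -
               gcnspForward(ah, xm, p)$logits[1]) / (2 * eps)
    # symmetric bump touches (i,j) and (j,i): equals twice the one-sided grad
    expect_equal(2 * es[i, j] / x[i, j], unname(gNum), tolerance = 1e-4)
  }
})

test_that("topEdges ranks the upper triangle with lexicographic ties", {
  es <- matrix(0, 5, 5)
  es[1, 3] <- es[3, 1] <- 2
  es[2, 4] <- es[4, 2] <- 2
  es[1, 5] <- es[5, 1] <- 1
  all10 <- topEdges(es, 1)
  expect_equal(nrow(all10), 10)
  expect_equal(all10$score[1:2], c(2, 2))
  expect_true(all10$i[1] == 1 && all10$j[1] == 3)  # (1,3) before (2,4)
  expect_equal(nrow(topEdges(es, 0.01)), 1)        # ceil(0.1) of 10 edges
  expect_equal(nrow(topEdges(matrix(0, 15, 15), 0.01)), 2)  # ceil(1.05)
})

test_that("network block weights equal brute-force block means", {
  part <- data.frame(roi_id = sprintf("ROI%03d", 1:6),
                     network = rep(c("DMN", "FPN"), each = 3))
  es <- randSym(6, seed = 9)
  edges <- topEdges(es, 1)
  nw <- networkWeights(edges, part)
  blocks <- list(DMN = 1:3, FPN = 4:6)
  for (a in names(blocks)) for (b in names(blocks)) {
    sel <- edges$i %in% blocks[[a]] & edges$j %in% blocks[[b]] |
      edges$i %in% blocks[[b]] & edges$j %in% blocks[[a]]
    expect_equal(nw[a, b], mean(edges$score[sel]))
  }
  expect_equal(nw, t(nw))
  # edges confined to one network: the other blocks are flagged missing
  one <- edges[edges$i <= 3 & edges$j <= 3, ]
  nw1 <- networkWeights(one, part)
  expect_false(is.na(nw1["DMN", "DMN"]))
  expect_true(is.na(nw1["FPN", "FPN"]) && is.na(nw1["DMN", "FPN"]))
})

test_that("group t statistics match the textbook formula", {
  a <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3)   # 3 elements x 3 subjects
  b <- matrix(c(0, 1, 2, 1, 2, 3, 1, 1, 1), 3)
  gd <- groupTTest(a, b)
  for (el in 1:3) {
    ref <- t.test(a[el, ], b[el, ], var.equal = TRUE)$statistic
    expect_equal(gd$t_values[el], unname(ref), tolerance = 1e-10)
  }
  # antisymmetry under group swap
  gd2 <- groupTTest(b, a)
  expect_equal(gd$t_values, -gd2$t_values)
  # identical groups: all differences vanish
  gd0 <- groupTTest(a, a)
  expect_equal(gd0$t_values, rep(0, 3))
  # degenerate constant elements: t forced to 0 with a warning
  expect_warning(gdc <- groupTTest(matrix(1, 2, 3), matrix(1, 2, 3)),
                 "zero pooled variance")
  expect_equal(gdc$t_values, rep(0, 2))
})

test_that("kernel density estimates are proper and calibrated", {
  set.seed(14)
  x <- rnorm(1e4)
  d <- kdeDensity(x)
  expect_true(all(d$density >= 0))
  expect_equal(sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2),
               1, tolerance = 1e-3)
  # against the standard normal reference at n = 10^4, averaged over
  # replicates (a single draw's max deviation fluctuates around this bound)
  devs <- vapply(1:5, function(s) {
    xs <- withr::with_seed(s, rnorm(1e4))
    ds <- kdeDensity(xs)
    max(abs(ds$density - dnorm(ds$grid)))
  }, 0)
  expect_lt(mean(devs), 0.02)
  # symmetric sample gives a symmetric curve about its mean
  xs <- c(-3, -1, -0.5, 0.5, 1, 3)
  g <- seq(-5, 5, length.out = 201)
  ds <- kdeDensity(xs, grid = g)
  expect_equal(ds$density, rev(ds$density), tolerance = 1e-6)
  # constant input survives through the bandwidth floor
  dc <- kdeDensity(rep(1, 5), grid = seq(0.9, 1.1, length.out = 11))
  expect_true(all(is.finite(dc$density)))
})

test_that("graph shuffles preserve the stated invariants", {
  fx <- smallSeparable()
  g <- buildKnnGraph(meanConnectivity(fx$ce), 5)
  a <- adjacency(g)
  s1 <- shuffleAdjacency(g, "adjacency", seed = 3)
  expect_equal(sum(adjacency(s1) > 0), sum(a > 0))      # edge count kept
  expect_equal(sort(adjacency(s1)[upper.tri(a)]), sort(a[upper.tri(a)]))
  s2 <- shuffleAdjacency(g, "node_order", seed = 3)
  expect_equal(sort(rowSums(adjacency(s2))), sort(rowSums(a)))
  expect_identical(adjacency(shuffleAdjacency(g, "adjacency", seed = 3)),
                   adjacency(s1))
  expect_false(identical(adjacency(s1), a))
})
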