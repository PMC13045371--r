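# Fixtures are built in code: small random symmetric matrices, toy
# multi-site datasets, and lightly trained models shared across tests.

# random symmetric zero-diagonal matrix
randSym <- function(n, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- rnorm(n * (n - 1) / 2, sd = sd)
    m + t(m)
  })
}

# tiny multi-site dataset from hand-drawn z matrices
toyCE <- function(nSubj = 8, n = 6, nSites = 2, seed = 1,
                  labels = rep(c("patient", "control"), length.out = nSubj)) {
  mats <- lapply(seq_len(nSubj), function(i) randSym(n, seed * 1000 + i, sd = 0.3))
  names(mats) <- sprintf("s%02d", seq_len(nSubj))
  ConnectomeExperiment(mats,
                       site = rep(sprintf("site%d", seq_len(nSites)),
                                  length.out = nSubj),
                       label = labels)
}

# a small separable dataset plus its population graph, memoised per session
smallSeparable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generateDataset(generatorConfig(
        nRois = 20L, nNetworks = 2L, nSites = 2L,
        nPatients = 10L, nControls = 10L, effectDelta = 0.4, seed = 42L))
      ce <- regressOutSite(gen$dataset)
      ah <- normalizeAdjacency(buildKnnGraph(meanConnectivity(ce), 5))
      cache <<- list(gen = gen, ce = ce, aHat = ah)
    }
    cache
  }
})

# a lightly trained small model for interpretability tests
smallModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- smallSeparable()
      hy <- gcnspHyper(hiddenSize = 8L, epochs = 40L, batchSize = 16L)
      cache <<- list(fit = trainGcnsp(fx$ce, fx$aHat, hy, seed = 9L), fx = fx)
    }
    cache
  }
})

# construct two time-series columns with an exact Pearson correlation r
tsWithCor <- function(r, t = 40, seed = 3) {
  withr::with_seed(seed, {
    u <- rnorm(t); v <- rnorm(t)
    u <- (u - mean(u)); u <- u / sqrt(sum(u^2))
    v <- v - mean(v) - u * sum(u * (v - mean(v)))
    v <- v / sqrt(sum(v^2))
    cbind(a = u, b = r * u + sqrt(1 - r^2) * v)
  })
}
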