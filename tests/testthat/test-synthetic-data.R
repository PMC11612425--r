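test_that("configs validate their invariants", {
  expect_error(tissueSimConfig(typeFreqs = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(tissueSimConfig(focalType = "nope"), "focalType")
  expect_error(tissueSimConfig(beta = -1), "non-negative")
  expect_error(tissueSimConfig(focalMixing = 2), "\\[0, 1\\]")
  expect_error(tissueSimConfig(saltPepperRate = 2), "\\[0, 1\\]")
})

test_that("cohorts are byte-identical across runs of the same seed", {
  cfg <- tissueSimConfig(samplesPerCondition = 2, cellsPerSample = 120,
                         centersPerSample = 12, seed = 77)
  a <- simulateTissue(cfg)
  b <- simulateTissue(cfg)
  expect_identical(a, b)
  # a different seed changes the cohort
  cfg2 <- tissueSimConfig(samplesPerCondition = 2, cellsPerSample = 120,
                          centersPerSample = 12, seed = 78)
  expect_false(identical(simulateTissue(cfg2)$x, a$x))
})

test_that("every sample carries the exact target type composition", {
  cfg <- tissueSimConfig(samplesPerCondition = 2, cellsPerSample = 200,
                         centersPerSample = 12, seed = 5)
  cells <- simulateTissue(cfg)
  target <- spatialhet:::largestRemainderCounts(cfg$typeFreqs, 200)
  for (s in unique(cells$sample_id)) {
    cnt <- table(factor(cells$cell_type[cells$sample_id == s],
                        levels = names(cfg$typeFreqs)))
    expect_equal(as.integer(cnt), unname(target), info = s)
  }
})

test_that("beta = 0 matches the random-labeling homophily expectation", {
  hs <- sapply(1:20, function(s) {
    cfg <- tissueSimConfig(conditions = "c1", samplesPerCondition = 1,
                           cellsPerSample = 400, beta = 0,
                           focalClustered = 0, focalMixing = 0,
                           centersPerSample = 12, seed = s)
    globalHomophily(buildDelaunayGraph(simulateTissue(cfg)))
  })
  # fixed composition: P(same type on a random pair) without replacement
  n <- 400
  cnt <- spatialhet:::largestRemainderCounts(
    tissueSimConfig()$typeFreqs, n)
  expected <- sum(cnt * (cnt - 1)) / (n * (n - 1))
  expect_lt(abs(mean(hs) - expected), 3 * sd(hs) / sqrt(length(hs)))
})

test_that("strong planting of two types produces near-segregated tissue", {
  eg <- sapply(1:3, function(s) {
    cfg <- tissueSimConfig(conditions = "c1", samplesPerCondition = 1,
                           cellsPerSample = 1500,
                           typeFreqs = c(A = 0.5, B = 0.5), focalType = "A",
                           beta = 50, focalClustered = 1, focalMixing = 0,
                           centersPerSample = 6, seed = s)
    mean(egophily(buildDelaunayGraph(simulateTissue(cfg)), 1))
  })
  expect_gt(mean(eg), 0.9)
})

test_that("raising the mixing parameter raises focal local entropy monotonically", {
  grid <- c(0, 1 / 3, 2 / 3, 1)
  means <- sapply(grid, function(m) {
    mean(sapply(1:10, function(s) {
      cfg <- tissueSimConfig(conditions = "case", samplesPerCondition = 1,
                             cellsPerSample = 300, centersPerSample = 12,
                             focalClustered = 0.7, focalMixing = m,
                             seed = 900 + s)
      sc <- computeAllScores(simulateTissue(cfg), radii = 5)
      mean(sc$value[sc$score == "local_entropy" & sc$cell_type == "Tcell"])
    }))
  })
  expect_equal(cor(grid, means, method = "spearman"), 1)
})

test_that("matched-parameter conditions give approximately uniform MWU p", {
  ps <- sapply(1:10, function(s) {
    cfg <- tissueSimConfig(conditions = c("u", "v"), samplesPerCondition = 4,
                           cellsPerSample = 200, centersPerSample = 12,
                           focalClustered = 0, focalMixing = 0, seed = 600 + s)
    sc <- computeAllScores(simulateTissue(cfg), radii = 5)
    tests <- testScores(sc)
    tests$p[!is.na(tests$cell_type) & tests$cell_type == "Tcell" &
              tests$score == "local_entropy"]
  })
  # under exchangeability the p values must not pile up near zero
  expect_gt(median(ps), 0.05)
  expect_lt(mean(ps < 0.01), 0.3)
})

test_that("clean rendering recovers exact abundance on own markers", {
  cfg <- tissueSimConfig(conditions = "c1", samplesPerCondition = 1,
                         cellsPerSample = 60, centersPerSample = 12,
                         exprRange = c(1, 1), backgroundRate = 0,
                         saltPepperRate = 0, orphanFraction = 0, seed = 3)
  cells <- simulateTissue(cfg)
  sim <- simulateChannels(cells, cfg)
  # no noise at all: binarize trivially by thresholding the raw channel
  bin <- lapply(sim$channels, function(ch) (ch > 100) * 1L)
  ab <- abundanceValues(abundanceMatrix(bin, sim$cellsMask))
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth$cell_type[i]
    lb <- as.character(sim$truth$label[i])
    if (!lb %in% rownames(ab)) next
    for (p in colnames(ab)) {
      expect_equal(unname(ab[lb, p]),
                   if (p == paste0("M_", t)) 1 else 0)
    }
  }
})

test_that("planted orphans are recovered by membrane completion", {
  cfg <- tissueSimConfig(conditions = "c1", samplesPerCondition = 1,
                         cellsPerSample = 80, centersPerSample = 12,
                         orphanFraction = 0.3, seed = 4)
  cells <- simulateTissue(cfg)
  sim <- simulateChannels(cells, cfg)
  expect_gt(sum(sim$truth$orphan), 0)
  expect_equal(length(unique(sim$cellsMask[sim$cellsMask > 0])),
               sum(!sim$truth$orphan))
  res <- completeMembranes(sim$nuclei, sim$cellsMask)
  expect_equal(length(unique(res$mask[res$mask > 0])), nrow(sim$truth))
  # orphan labels preserved when free, enabling truth lookup
  expect_setequal(unique(res$mask[res$mask > 0]), sim$truth$label)
})

test_that("designed references rank each type's own marker first", {
  panel <- data.frame(type = c("alpha", "beta", "gamma"),
                      gene = c("G1", "G2", "G3"))
  ref <- simulateReference(panel, seed = 6)
  s <- spreadScores(ref)
  for (i in seq_len(nrow(panel))) {
    expect_equal(colnames(s)[which.max(s[panel$type[i], ])], panel$gene[i])
  }
  # single cluster per type: type values equal the cluster values
  ref1 <- simulateReference(panel, seed = 6, extraTypes = NULL)
  expect_s4_class(ref1, "ReferenceExpression")
  # aggregation is invariant to cluster order
  perm <- sample(nrow(ref@clusterExpr))
  ref2 <- referenceExpression(ref@clusterExpr[perm, ],
                              ref@clusterSizes[perm],
                              ref@clusterTypes[perm])
  expect_equal(typeExpression(ref2), typeExpression(ref))
})
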