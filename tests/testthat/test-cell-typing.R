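# direct sampler of a designed abundance matrix: each type expresses its
# own marker in a per-cell fraction, everything else stays near zero
sampleAbundance <- function(nPerType, types, seed = 1) {
  withr::local_seed(seed)
  truth <- rep(types, nPerType)
  n <- length(truth)
  A <- matrix(rbinom(n * length(types), 50, 0.004) / 50,
              nrow = n, ncol = length(types),
              dimnames = list(sprintf("cell%03d", seq_len(n)),
                              paste0("G", seq_along(types))))
  for (k in seq_along(types)) {
    own <- which(truth == types[k])
    A[own, k] <- pmin(1, runif(length(own), 0.55, 0.95) +
                        rnorm(length(own), 0, 0.02))
  }
  list(A = A, truth = setNames(truth, rownames(A)))
}

designedReference <- function(types, seed = 1) {
  panel <- data.frame(type = types, gene = paste0("G", seq_along(types)))
  simulateReference(panel, seed = seed)
}

test_that("reference aggregation is the size-weighted cluster mean", {
  m <- rbind(c1 = c(g = 2), c2 = c(g = 6))
  expect_equal(unname(aggregateReference(m, c(10, 30), c("t", "t"))[1, 1]), 5)
  expect_equal(unname(aggregateReference(m[1, , drop = FALSE], 10, "t")[1, 1]), 2)
  expect_equal(unname(aggregateReference(m, c(7, 7), c("t", "t"))[1, 1]), 4)
  expect_error(aggregateReference(m, c(0, 0), c("t", "t")), "positive")
})

test_that("the HPA-dialect reader filters tissue and aggregates clusters", {
  ex <- system.file("extdata", "synthetic_hpa_expression.tsv",
                    package = "spatialhet")
  cl <- system.file("extdata", "synthetic_hpa_clusters.tsv",
                    package = "spatialhet")
  ref <- readHPAReference(ex, cl, tissue = "skin")
  expect_s4_class(ref, "ReferenceExpression")
  expect_setequal(referenceTypes(ref),
                  c("T-cells", "basal keratinocytes", "endothelial cells"))
  # two T-cell clusters of sizes 120 and 40: weighted mean of CD3E
  expect_equal(unname(typeExpression(ref)["T-cells", "CD3E"]),
               (120 * 52 + 40 * 46) / 160)
  # the lung cluster must not leak in
  expect_false(any(typeExpression(ref) == 99))
})

test_that("spread scores subtract the best other remaining type", {
  X <- rbind(t1 = 5, t2 = 1, t3 = 0)
  colnames(X) <- "g"
  s <- spreadScores(X)
  expect_equal(unname(s[, "g"]), c(4, -4, -5))

  tie <- rbind(a = 3, b = 3); colnames(tie) <- "g"
  expect_equal(unname(spreadScores(tie)[, "g"]), c(0, 0))

  # removing the runner-up weakly increases every remaining spread
  s2 <- spreadScores(X, types = c("t1", "t3"))
  expect_gte(s2["t1", "g"], s["t1", "g"])
  expect_gte(s2["t3", "g"], s["t3", "g"])

  expect_error(spreadScores(X, types = "t1"), "at least two")
})

test_that("the bimodal separation gate matches its closed form", {
  expect_true(isWellSeparated(0.1, 0.02, 0.6, 0.1))   # 0.1392 < 0.404
  expect_false(isWellSeparated(0.3, 0.1, 0.5, 0.1))   # 0.496 < 0.304 fails
})

test_that("mixture fits recover planted components and gate unimodal data", {
  withr::local_seed(18)
  v <- c(rnorm(1000, 0.05, 0.01), rnorm(1000, 0.8, 0.05))
  f <- fitBimodal(v, seed = 3)
  expect_true(f$good)
  expect_lt(abs(f$mu0 - 0.05), 0.02)
  expect_lt(abs(f$mu1 - 0.80), 0.02)
  expect_identical(fitBimodal(v, seed = 3), f)  # seeded determinism

  f2 <- fitBimodal(rnorm(500, 0.3, 0.05), seed = 3)
  expect_false(f2$good)

  expect_false(fitBimodal(c(0.1, 0.9), seed = 1)$good)  # too few
  # constant data: degenerate components are never good
  expect_false(fitBimodal(rep(0.5, 100), seed = 1)$good)
})

test_that("assignment recovers designed types and audits its thresholds", {
  types <- c("alpha", "beta", "gamma")
  sim <- sampleAbundance(c(60, 60, 60), types, seed = 4)
  # markerless cells that must end up unknown
  withr::local_seed(40)
  extra <- matrix(rbinom(30 * 3, 50, 0.004) / 50, nrow = 30,
                  dimnames = list(sprintf("noise%02d", 1:30), colnames(sim$A)))
  A <- rbind(sim$A, extra)
  truth <- c(sim$truth, setNames(rep("unknown", 30), rownames(extra)))
  ref <- designedReference(types, seed = 4)
  res <- assignCellTypes(A, ref, seed = 11)
  expect_gte(mean(res$labels[names(truth)] == truth), 0.98)
  # partition: one label per input cell, in input order
  expect_identical(names(res$labels), rownames(A))
  # termination within |Sigma| iterations
  expect_lte(nrow(res$log), length(referenceTypes(ref)))
  # audit: the applied threshold equals mu1 - 1.96 sigma1 of the logged fit
  expect_equal(res$log$threshold,
               res$log$mu1 - 1.96 * res$log$sigma1, tolerance = 1e-12)
  # first-iteration assignment reproducible from the log
  g1 <- res$log$gene[1]
  assigned1 <- names(res$labels)[res$labels == res$log$cell_type[1]]
  expect_setequal(assigned1, rownames(A)[A[, g1] > res$log$threshold[1]])
})

test_that("assignment is invariant to the input row order", {
  types <- c("alpha", "beta")
  sim <- sampleAbundance(c(50, 50), types, seed = 6)
  ref <- designedReference(types, seed = 6)
  r1 <- assignCellTypes(sim$A, ref, seed = 2)
  withr::local_seed(1)
  perm <- sample(nrow(sim$A))
  r2 <- assignCellTypes(sim$A[perm, ], ref, seed = 2)
  expect_identical(r1$labels[rownames(sim$A)], r2$labels[rownames(sim$A)])
})

test_that("all-unimodal abundances produce zero iterations and all unknown", {
  withr::local_seed(19)
  A <- matrix(rnorm(200 * 3, 0.3, 0.03), nrow = 200,
              dimnames = list(sprintf("c%03d", 1:200), paste0("G", 1:3)))
  A[A < 0] <- 0; A[A > 1] <- 1
  ref <- designedReference(c("alpha", "beta", "gamma"), seed = 2)
  res <- assignCellTypes(A, ref, seed = 5)
  expect_equal(nrow(res$log), 0L)
  expect_true(all(res$labels == "unknown"))
  expect_match(res$stopReason, "no good genes")
})

test_that("gene mapping is case-insensitive and prunes unmatched proteins", {
  types <- c("alpha", "beta")
  sim <- sampleAbundance(c(40, 40), types, seed = 7)
  # markerless cells keep the pool bimodal after the first assignment
  withr::local_seed(70)
  extra <- matrix(rbinom(30 * 2, 50, 0.004) / 50, nrow = 30,
                  dimnames = list(sprintf("noise%02d", 1:30),
                                  colnames(sim$A)))
  A <- rbind(sim$A, extra)
  truth <- c(sim$truth, setNames(rep("unknown", 30), rownames(extra)))
  colnames(A) <- c("AB_ONE", "ab_two")
  ref <- designedReference(types, seed = 7)
  gm <- data.frame(protein = c("ab_one", "AB_TWO", "spare"),
                   gene = c("g1", "g2", "g9"))
  res <- assignCellTypes(A, ref, geneMap = gm, seed = 3)
  expect_gte(mean(res$labels[names(truth)] == truth), 0.97)

  badMap <- data.frame(protein = c("x", "y"), gene = c("zz", "ww"))
  expect_error(suppressWarnings(
    assignCellTypes(sim$A, ref, geneMap = badMap)), "no overlap")
})

test_that("a lone remaining type stops the protocol with unknowns", {
  # reference with 2 types but only one informative marker present
  types <- c("alpha", "beta")
  sim <- sampleAbundance(c(50, 50), types, seed = 8)
  A <- sim$A[, 1, drop = FALSE]  # only alpha's marker measured
  ref <- designedReference(types, seed = 8)
  res <- assignCellTypes(A, ref, seed = 3)
  expect_lte(nrow(res$log), 1L)
  expect_match(res$stopReason, "single remaining type|no good genes")
  expect_true(all(res$labels[sim$truth == "beta"] == "unknown"))
})
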