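test_that("global entropy matches hand-computed values and degeneracies", {
  g <- pathGraph(c("A", "A", "B", "C"))
  expect_equal(globalEntropy(g), 0.9464, tolerance = 1e-4)

  mono <- spatialCellGraph(letters[1:4], cbind(1:3, 2:4), rep("A", 4),
                          typeUniverse = c("A", "B", "C"))
  expect_equal(globalEntropy(mono), 0)

  # equal counts over the full universe maximize normalized entropy
  uni <- pathGraph(c("A", "B", "C"))
  expect_equal(globalEntropy(uni), 1)

  # |T| = 1: no heterogeneity representable
  one <- spatialCellGraph(letters[1:3], cbind(1:2, 2:3), rep("A", 3))
  expect_equal(globalEntropy(one), 0)
})

test_that("global homophily is the monochromatic edge fraction", {
  expect_equal(globalHomophily(pathGraph(c("A", "A", "B"))), 0.5)
  expect_equal(globalHomophily(pathGraph(rep("Z", 5))), 1)
  # complete bipartite between the two type classes
  bip <- spatialCellGraph(letters[1:4],
                         rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4)),
                         c("A", "A", "B", "B"))
  expect_equal(globalHomophily(bip), 0)
  edgeless <- spatialCellGraph(letters[1:3], matrix(integer(0), ncol = 2),
                              rep("A", 3))
  expect_error(globalHomophily(edgeless), "edgeless")
})

test_that("star and path worked examples give the documented local scores", {
  star <- starGraph(3)
  expect_equal(unname(localEntropy(star, 1)["hub"]), 0.8113, tolerance = 1e-4)
  expect_equal(unname(egophily(star, 1)["hub"]), 0.25)
  expect_equal(unname(egophily(star, 1)["leaf1"]), 0.5)
  expect_equal(unname(localHomophily(star, 1)["hub"]), 0)

  path <- pathGraph(c("A", "A", "B", "B"))
  expect_equal(unname(localHomophily(path, 1)["b"]), 0.5)
})

test_that("a single-type neighborhood has zero local entropy", {
  g <- pathGraph(c("A", "A", "A", "B"))
  expect_equal(unname(localEntropy(g, 1)["a"]), 0)
})

test_that("local homophily is missing exactly for empty induced edge sets", {
  # vertex d is isolated: its neighborhood is the singleton {d}
  g <- spatialCellGraph(letters[1:4], cbind(c(1, 2), c(2, 3)),
                       c("A", "B", "A", "B"))
  h <- localHomophily(g, 1)
  expect_true(is.na(h[["d"]]))
  expect_false(anyNA(h[c("a", "b", "c")]))
})

test_that("local scores converge to global scores at r >= diameter", {
  withr::local_seed(42)
  n <- 80
  cells <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      x = runif(n) * 100, y = runif(n) * 100,
                      cell_type = sample(c("A", "B", "C"), n, replace = TRUE))
  g <- buildDelaunayGraph(cells)
  r <- n  # certainly >= diameter
  expect_equal(unname(localEntropy(g, r)), rep(globalEntropy(g), n),
               tolerance = 1e-12)
  expect_equal(unname(localHomophily(g, r)), rep(globalHomophily(g), n),
               tolerance = 1e-12)
})

test_that("egophily respects its self-inclusion lower bound", {
  g <- randomLabeledGraph(50, 4, pEdge = 0.05, seed = 9)
  e <- egophily(g, 2)
  sizes <- localScores(g, 2)$size[, 1]
  expect_true(all(e >= 1 / sizes))
  expect_true(all(e > 0))
  mono <- pathGraph(rep("A", 5))
  expect_equal(unname(egophily(mono, 1)), rep(1, 5))
})

test_that("scores are equivariant under relabeling bijections", {
  g <- randomLabeledGraph(60, 3, pEdge = 0.06, seed = 21)
  # bijection A->B, B->C, C->A
  perm <- c(A = "B", B = "C", C = "A")
  g2 <- spatialCellGraph(cellIds(g), edgeMatrix(g),
                        unname(perm[cellTypes(g)]),
                        typeUniverse = c("A", "B", "C"))
  expect_equal(globalEntropy(g), globalEntropy(g2), tolerance = 1e-12)
  expect_equal(globalHomophily(g), globalHomophily(g2), tolerance = 1e-12)
  for (r in c(1, 3)) {
    expect_equal(unname(localEntropy(g, r)), unname(localEntropy(g2, r)),
                 tolerance = 1e-12)
    expect_equal(unname(localHomophily(g, r)), unname(localHomophily(g2, r)),
                 tolerance = 1e-12)
    expect_equal(unname(egophily(g, r)), unname(egophily(g2, r)),
                 tolerance = 1e-12)
  }
})

test_that("vectorized local scores match the naive per-cell reference", {
  for (s in 1:15) {
    withr::local_seed(400 + s)
    n <- sample(10:60, 1)
    g <- randomLabeledGraph(n, sample(2:5, 1), pEdge = 0.08, seed = 400 + s)
    for (r in c(1, 2, 5)) {
      ref <- naiveLocalScores(g, r)
      expect_equal(localEntropy(g, r), ref$entropy, tolerance = 1e-12)
      expect_equal(localHomophily(g, r), ref$homophily, tolerance = 1e-12)
      expect_equal(egophily(g, r), ref$egophily, tolerance = 1e-12)
    }
  }
})

test_that("all scores stay within [0, 1] wherever defined", {
  g <- randomLabeledGraph(100, 5, pEdge = 0.03, seed = 5)
  for (r in c(1, 4)) {
    sc <- localScores(g, r)
    for (nm in c("entropy", "homophily", "egophily")) {
      v <- sc[[nm]][!is.na(sc[[nm]])]
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("computeAllScores has the documented shape and is order invariant", {
  withr::local_seed(31)
  n <- 40
  cells <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      x = runif(n) * 100, y = runif(n) * 100,
                      sample_id = "s1", condition = "case",
                      cell_type = sample(c("A", "B"), n, replace = TRUE))
  sc <- computeAllScores(cells, radii = c(1, 2))
  expect_equal(nrow(sc), 2 + 3 * 2 * n)
  expect_setequal(unique(sc$score),
                  c("global_entropy", "global_homophily",
                    "local_entropy", "local_homophily", "egophily"))

  sc2 <- computeAllScores(cells[sample(n), ], radii = c(1, 2))
  expect_equal(sc, sc2, ignore_attr = TRUE)

  # every value matches the single-score operations
  g <- buildDelaunayGraph(cells, typeUniverse = attr(sc, "typeUniverse"))
  expect_equal(sc$value[sc$score == "global_entropy"], globalEntropy(g))
  le <- localEntropy(g, 2)
  sub <- sc[sc$score == "local_entropy" & sc$radius == 2, ]
  expect_equal(sub$value, unname(le[sub$cell_id]), tolerance = 1e-12)
  eg <- egophily(g, 1)
  sub <- sc[sc$score == "egophily" & sc$radius == 1, ]
  expect_equal(sub$value, unname(eg[sub$cell_id]), tolerance = 1e-12)
})

test_that("unscorable samples are reported and skipped, not dropped silently", {
  withr::local_seed(32)
  good <- data.frame(cell_id = sprintf("g%02d", 1:20),
                     x = runif(20) * 50, y = runif(20) * 50,
                     sample_id = "ok", condition = "case", cell_type = "A")
  bad <- data.frame(cell_id = c("b1", "b2"), x = c(0, 1), y = c(0, 1),
                    sample_id = "tiny", condition = "case", cell_type = "A")
  expect_warning(sc <- computeAllScores(rbind(good, bad), radii = 1),
                 "skipped.*tiny")
  expect_setequal(unique(sc$sample_id), "ok")
  expect_true("tiny" %in% names(attr(sc, "skipped")))
})

test_that("score tables round-trip through the CSV dialect", {
  withr::local_seed(33)
  n <- 15
  cells <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      x = runif(n) * 50, y = runif(n) * 50,
                      sample_id = "s1", condition = "case",
                      cell_type = sample(c("A", "B"), n, replace = TRUE))
  sc <- computeAllScores(cells, radii = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  writeScoreTable(sc, path)
  raw <- read.csv(path, colClasses = "character")
  expect_true(all(raw$radius[raw$score == "global_entropy"] == "global"))
  back <- readScoreTable(path)
  expect_equal(back$value, sc$value)
  expect_equal(back$radius, sc$radius)
})
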