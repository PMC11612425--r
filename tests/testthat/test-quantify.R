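test_that("adaptive binarization handles degenerate inputs", {
  expect_true(all(adaptiveBinarize(matrix(5, 20, 20), window = 9) == 0))
  expect_error(adaptiveBinarize(matrix(1, 10, 10), window = 8), "odd")
  expect_error(adaptiveBinarize(matrix(1, 10, 10), window = 1), "odd|>= 3")
})

test_that("an isolated bright pixel binarizes to 1 under a wide window", {
  y <- matrix(0, 250, 250)
  y[125, 125] <- 1000
  b <- adaptiveBinarize(y, window = 201)
  expect_equal(b[125, 125], 1L)
  expect_equal(sum(b), 1L)
})

test_that("binarization equals the naive sliding-window reference bit for bit", {
  withr::local_seed(14)
  x <- matrix(runif(40 * 40), 40, 40)
  b <- adaptiveBinarize(x, window = 7, offset = 0.3)
  ref <- naiveAdaptiveBinarize(x, 7, attr(b, "sigma"), 0.3)
  expect_identical(as.vector(b), as.vector(ref))
  expect_gt(sum(b), 0)  # the comparison is not vacuous
})

test_that("binarization with the default offset uses the channel std", {
  withr::local_seed(15)
  x <- matrix(rnorm(30 * 30, 100, 10), 30, 30)
  b <- adaptiveBinarize(x, window = 9)
  expect_equal(attr(b, "offset"), sd(as.vector(x)))
})

test_that("abundance fractions equal per-pixel tallies", {
  seg <- matrix(0L, 4, 4)
  seg[1:2, 1:2] <- 1L  # 4-pixel segment
  ch <- matrix(0L, 4, 4)
  ch[1, 1] <- ch[1, 2] <- ch[2, 1] <- 1L
  ab <- abundanceMatrix(list(p1 = ch), seg)
  expect_equal(unname(abundanceValues(ab)[1, 1]), 0.75)

  ones <- matrix(1L, 4, 4)
  ab2 <- abundanceMatrix(list(p1 = ones), seg)
  expect_equal(unname(abundanceValues(ab2)[1, 1]), 1)

  # random mask + random channel against a brute-force loop
  withr::local_seed(16)
  seg <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  ch <- matrix(rbinom(100, 1, 0.4), 10, 10)
  ab3 <- abundanceValues(abundanceMatrix(list(p = ch), seg))
  for (lb in 1:3) {
    expect_equal(unname(ab3[as.character(lb), "p"]),
                 sum(ch[seg == lb]) / sum(seg == lb))
  }

  expect_error(abundanceMatrix(list(p = matrix(0, 3, 3)), seg), "shape")
  expect_error(abundanceMatrix(list(matrix(0, 10, 10)), seg), "named")
})

# build a rectangular segment mask block
putRect <- function(m, r0, c0, h, w, value) {
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- value
  m
}

test_that("membrane completion reproduces the radius-ratio rule", {
  # matched pairs with area ratios (6/4)^2 and (12/8)^2 -> rho = 1.5
  nuc <- matrix(0L, 60, 60)
  cells <- matrix(0L, 60, 60)
  nuc <- putRect(nuc, 5, 5, 4, 4, 1L)      # nucleus area 16
  cells <- putRect(cells, 3, 3, 6, 6, 10L) # cell area 36
  nuc <- putRect(nuc, 30, 30, 8, 8, 2L)    # nucleus area 64
  cells <- putRect(cells, 28, 28, 12, 12, 20L)  # cell area 144
  nuc <- putRect(nuc, 15, 45, 4, 4, 3L)    # orphan, area 16
  res <- completeMembranes(nuc, cells)
  expect_equal(res$rho, 1.5)
  # the orphan receives a disc of radius rho * sqrt(16/pi) around its centroid
  rad <- 1.5 * sqrt(16 / pi)
  cy <- mean(15:18); cx <- mean(45:48)
  disc <- which(outer((1:60 - cy)^2, (1:60 - cx)^2, "+") <= rad^2 &
                  cells == 0L)
  expect_setequal(which(res$mask == 3L), disc)
  # detected cells kept verbatim; one new segment per orphan
  expect_equal(sum(res$mask == 10L), 36)
  expect_equal(sum(res$mask == 20L), 144)
  expect_setequal(unique(as.vector(res$mask[res$mask > 0])), c(3, 10, 20))
})

test_that("completion without orphans returns the detected cells unchanged", {
  nuc <- putRect(matrix(0L, 20, 20), 5, 5, 3, 3, 1L)
  cells <- putRect(matrix(0L, 20, 20), 4, 4, 6, 6, 7L)
  res <- completeMembranes(nuc, cells)
  expect_identical(res$mask, cells)
  expect_false(any(res$mapping$orphan))
})

test_that("contested pixels go to the nearer centroid and masks stay disjoint", {
  nuc <- matrix(0L, 40, 40)
  cells <- matrix(0L, 40, 40)
  # one matched pair defining rho = 2 (areas 9 -> 36)
  nuc <- putRect(nuc, 2, 2, 3, 3, 1L)
  cells <- putRect(cells, 1, 1, 6, 6, 5L)
  # two orphan nuclei close together: their discs overlap
  nuc <- putRect(nuc, 20, 18, 3, 3, 2L)
  nuc <- putRect(nuc, 20, 24, 3, 3, 3L)
  res <- completeMembranes(nuc, cells)
  expect_equal(res$rho, 2)
  m <- res$mask
  # disjointness is structural; check both orphans produced segments and
  # every contested pixel ended with its nearer centroid
  expect_gt(sum(m == 2L), 0)
  expect_gt(sum(m == 3L), 0)
  c2 <- c(mean(20:22), mean(18:20))  # (row, col)
  c3 <- c(mean(20:22), mean(24:26))
  idx2 <- which(m == 2L, arr.ind = TRUE)
  idx3 <- which(m == 3L, arr.ind = TRUE)
  d <- function(idx, ce) (idx[, 1] - ce[1])^2 + (idx[, 2] - ce[2])^2
  expect_true(all(d(idx2, c2) <= d(idx2, c3)))
  expect_true(all(d(idx3, c3) <= d(idx3, c2)))
  # segment count: detected + orphans
  expect_equal(length(unique(m[m > 0])), 3L)
})

test_that("invalid nucleus/cell topologies are rejected", {
  nuc <- matrix(0L, 20, 20)
  cells <- matrix(0L, 20, 20)
  # nucleus spanning two detected cells
  nuc <- putRect(nuc, 5, 5, 2, 6, 1L)
  cells <- putRect(cells, 4, 4, 4, 4, 7L)
  cells <- putRect(cells, 4, 8, 4, 4, 8L)
  expect_error(completeMembranes(nuc, cells), "two or more detected cells")

  # no matched pair at all
  nuc2 <- putRect(matrix(0L, 20, 20), 5, 5, 3, 3, 1L)
  expect_error(completeMembranes(nuc2, matrix(0L, 20, 20)), "radius ratio")

  # one detected cell containing two nuclei
  nuc3 <- matrix(0L, 20, 20)
  nuc3 <- putRect(nuc3, 5, 5, 2, 2, 1L)
  nuc3 <- putRect(nuc3, 9, 9, 2, 2, 2L)
  cells3 <- putRect(matrix(0L, 20, 20), 4, 4, 8, 8, 7L)
  expect_error(completeMembranes(nuc3, cells3), "two or more nuclei")

  expect_error(completeMembranes(matrix(0L, 5, 5), matrix(0L, 6, 6)), "shape")
})

test_that("quantifyAbundance records binarization metadata", {
  withr::local_seed(17)
  seg <- putRect(matrix(0L, 30, 30), 10, 10, 5, 5, 1L)
  ch <- matrix(rnorm(900, 50, 5), 30, 30)
  ch[10:14, 10:14] <- 300
  ab <- quantifyAbundance(list(pA = ch), seg, window = 11)
  expect_s4_class(ab, "AbundanceMatrix")
  expect_equal(ab@window, 11L)
  expect_equal(unname(ab@offsets["pA"]), sd(as.vector(ch)))
  expect_gt(abundanceValues(ab)[1, 1], 0.9)
})
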