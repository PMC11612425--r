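#' Two-sided Mann-Whitney U test
#'
#' Thin, policy-carrying wrapper around [stats::wilcox.test()]: the
#' exact null distribution is used for small untied samples
#' (`n1 * n2 <= exactMax` and no ties), and the tie-corrected normal
#' approximation with continuity correction otherwise.  Missing values
#' are dropped, with the dropped count recorded in the result.
#'
#' @param x,y numeric score samples.
#' @param exactMax exact-distribution switch threshold on `n1 * n2`.
#' @param stratum optional label used in error messages.
#' @return a list with `U` (the Mann-Whitney statistic for `x`), `p`,
#'   `n1`, `n2`, `exact` and `nDropped`.
#' @export
mwuTest <- function(x, y, exactMax = 400L, stratum = NULL) {
  xin <- as.numeric(x); yin <- as.numeric(y)
  x <- xin[!is.na(xin)]; y <- yin[!is.na(yin)]
  nDropped <- (length(xin) - length(x)) + (length(yin) - length(y))
  if (!length(x) || !length(y))
    stop("group with zero non-missing values",
         if (!is.null(stratum)) paste0(" in stratum ", stratum) else "")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (as.double(n1) * n2 <= exactMax) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, n1 = n1, n2 = n2,
       exact = exact, nDropped = nDropped)
}

#' Bonferroni-corrected significance cutoff
#'
#' The family-wise cutoff `alpha / m` with family size `m = nPairs *
#' nCellTypes * nRadii` (factors default to 1, so the global-score
#' family uses `m = nPairs`).
#'
#' @param alpha nominal level (default 0.05).
#' @param nPairs number of condition pairs.
#' @param nCellTypes number of cell types in the local family.
#' @param nRadii number of tested radii in the local family.
#' @return the cutoff `alpha / m`.
#' @examples
#' bonferroniCutoff(0.05, nPairs = 3, nCellTypes = 11, nRadii = 10)
#' @export
bonferroniCutoff <- function(alpha = 0.05, nPairs = 1L, nCellTypes = 1L,
                             nRadii = 1L) {
  alpha / (nPairs * nCellTypes * nRadii)
}

globalScoreNames <- c("global_entropy", "global_homophily")
localScoreNames <- c("local_entropy", "local_homophily", "egophily")

# pooled per-condition value vectors for one local stratum
poolLocal <- function(scores, score, cellType, radius, bySampleMedian = FALSE) {
  sel <- scores$score == score & !is.na(scores$radius) &
    scores$radius == radius & scores$cell_type == cellType
  sub <- scores[which(sel), , drop = FALSE]
  if (bySampleMedian) {
    med <- tapply(sub$value, sub$sample_id, stats::median, na.rm = TRUE)
    cond <- tapply(as.character(sub$condition), sub$sample_id, `[`, 1)
    split(as.numeric(med), as.character(cond))
  } else {
    split(sub$value, as.character(sub$condition))
  }
}

#' Differential testing of heterogeneity scores between conditions
#'
#' For each global score and condition pair, a two-sided MWU test on
#' the per-sample values, Bonferroni-corrected with family size
#' `m = number of condition pairs`.  For each local score, radius,
#' cell type and condition pair, an MWU test on the cells pooled
#' across all samples of each condition, with family size
#' `m = pairs x cell types x radii` (per score type).  Missing local
#' homophily values are dropped pairwise; strata where a cell type is
#' absent in one condition are skipped and reported in the `skipped`
#' attribute.
#'
#' @param scores a score table from [computeAllScores()].
#' @param alpha nominal level used for the `significant` column.
#' @param bySampleMedian if `TRUE`, local tests compare per-sample
#'   medians instead of pooled cells (a deviation option; the default
#'   pools cells).
#' @param nCellTypesFamily,nRadiiFamily optional overrides for the
#'   local family factors (defaults: the numbers observed in `scores`).
#' @return data.frame of test results: `score`, `radius`, `cell_type`,
#'   `cond_a`, `cond_b`, `n_a`, `n_b`, `U`, `p`, `m`, `p_adj`,
#'   `significant`; with attribute `skipped`.
#' @export
testScores <- function(scores, alpha = 0.05, bySampleMedian = FALSE,
                       nCellTypesFamily = NULL, nRadiiFamily = NULL) {
  conds <- sort(unique(as.character(scores$condition)))
  if (length(conds) < 2) stop("need at least two conditions")
  pairs <- combn(conds, 2)
  nPairs <- ncol(pairs)
  res <- list()
  skipped <- character(0)

  gl <- scores[scores$score %in% globalScoreNames, , drop = FALSE]
  for (sc in intersect(globalScoreNames, unique(gl$score))) {
    sub <- gl[gl$score == sc, , drop = FALSE]
    for (k in seq_len(nPairs)) {
      a <- pairs[1, k]; b <- pairs[2, k]
      x <- sub$value[sub$condition == a]
      y <- sub$value[sub$condition == b]
      t <- mwuTest(x, y, stratum = sprintf("%s %s vs %s", sc, a, b))
      res[[length(res) + 1]] <- data.frame(
        score = sc, radius = NA_integer_, cell_type = NA_character_,
        cond_a = a, cond_b = b, n_a = t$n1, n_b = t$n2, U = t$U, p = t$p,
        m = nPairs, stringsAsFactors = FALSE)
    }
  }

  lo <- scores[scores$score %in% localScoreNames, , drop = FALSE]
  if (nrow(lo)) {
    radii <- sort(unique(lo$radius))
    types <- sort(unique(lo$cell_type))
    mLocal <- nPairs * (nCellTypesFamily %||% length(types)) *
      (nRadiiFamily %||% length(radii))
    for (sc in intersect(localScoreNames, unique(lo$score))) {
      for (r in radii) {
        for (ct in types) {
          groups <- poolLocal(lo, sc, ct, r, bySampleMedian)
          for (k in seq_len(nPairs)) {
            a <- pairs[1, k]; b <- pairs[2, k]
            x <- groups[[a]]; y <- groups[[b]]
            x <- x[!is.na(x)]; y <- y[!is.na(y)]
            if (!length(x) || !length(y)) {
              skipped <- c(skipped, sprintf(
                "%s r=%d type=%s %s vs %s: cell type absent in one condition",
                sc, r, ct, a, b))
              next
            }
            t <- mwuTest(x, y)
            res[[length(res) + 1]] <- data.frame(
              score = sc, radius = r, cell_type = ct,
              cond_a = a, cond_b = b, n_a = t$n1, n_b = t$n2, U = t$U,
              p = t$p, m = mLocal, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(res)) stop("no testable strata in the score table")
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$m * out$p)
  out$significant <- out$p_adj < alpha
  if (length(skipped))
    message("testScores: skipped ", length(skipped), " stratum/strata")
  attr(out, "skipped") <- skipped
  out
}

# sample -> condition lookup from a score table
sampleConditions <- function(scores) {
  u <- unique(scores[, c("sample_id", "condition")])
  setNames(as.character(u$condition), u$sample_id)
}

# per-sample value lists for the local strata used by the robustness tests
localStrataData <- function(scores, scoreNames, radius, cellTypes) {
  lo <- scores[scores$score %in% scoreNames & !is.na(scores$radius) &
                 scores$radius == radius, , drop = FALSE]
  if (!is.null(cellTypes))
    lo <- lo[lo$cell_type %in% cellTypes, , drop = FALSE]
  if (!nrow(lo)) stop("no local score rows for the requested strata")
  split(lo, list(lo$score, lo$cell_type), drop = TRUE, sep = "\r")
}

robustnessStratum <- function(sub, sampleCond, pairs) {
  bySample <- split(sub$value, as.character(sub$sample_id))
  function(condOf) {
    out <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      x <- unlist(bySample[names(condOf)[condOf == a]], use.names = FALSE)
      y <- unlist(bySample[names(condOf)[condOf == b]], use.names = FALSE)
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      out[k] <- if (length(x) && length(y)) mwuTest(x, y)$p else NA_real_
    }
    out
  }
}

#' Label-permutation robustness test
#'
#' Shuffles the condition labels across all samples (preserving the
#' original group sizes), recomputes the pooled-cell MWU p value per
#' stratum, and repeats.  p values are reported unadjusted, alongside
#' the p value for the original labels.
#'
#' @param scores a score table from [computeAllScores()].
#' @param scoreNames local scores to test.
#' @param radius hop radius of the tested stratum (default 5).
#' @param cellTypes cell types to test (default: all present).
#' @param iterations number of permutations (default 100).
#' @param seed RNG seed.
#' @return data.frame with one row per stratum x condition pair x
#'   iteration: `score`, `cell_type`, `cond_a`, `cond_b`, `iteration`,
#'   `p`, `original_p`; attributes `mode`, `iterations`, `seed`.  With
#'   `iterations = 0`, a zero-row frame whose `original` attribute
#'   still carries the original p values.
#' @export
permutationTest <- function(scores, scoreNames = localScoreNames,
                            radius = 5L, cellTypes = NULL,
                            iterations = 100L, seed = 1L) {
  condOf <- sampleConditions(scores)
  if (length(condOf) < length(unique(condOf)))
    stop("fewer samples than conditions")
  conds <- sort(unique(condOf))
  pairs <- combn(conds, 2)
  strata <- localStrataData(scores, scoreNames, radius, cellTypes)
  pfuns <- lapply(strata, robustnessStratum, sampleCond = condOf, pairs = pairs)
  orig <- lapply(pfuns, function(f) f(condOf))
  key <- do.call(rbind, strsplit(names(strata), "\r", fixed = TRUE))
  origDf <- data.frame(
    score = rep(key[, 1], each = ncol(pairs)),
    cell_type = rep(key[, 2], each = ncol(pairs)),
    cond_a = rep(pairs[1, ], length(strata)),
    cond_b = rep(pairs[2, ], length(strata)),
    original_p = unlist(orig, use.names = FALSE), stringsAsFactors = FALSE)
  rows <- withSeed(seed, {
    lapply(seq_len(iterations), function(it) {
      perm <- setNames(sample(unname(condOf)), names(condOf))
      ps <- lapply(pfuns, function(f) f(perm))
      cbind(origDf[, c("score", "cell_type", "cond_a", "cond_b")],
            iteration = it, p = unlist(ps, use.names = FALSE))
    })
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(origDf[0, c("score", "cell_type", "cond_a", "cond_b")],
          iteration = integer(0), p = numeric(0))
  out <- merge(out, origDf, by = c("score", "cell_type", "cond_a", "cond_b"),
               sort = TRUE)
  out <- out[order(out$score, out$cell_type, out$cond_a, out$cond_b,
                   out$iteration), ]
  rownames(out) <- NULL
  attr(out, "original") <- origDf
  attr(out, "mode") <- "permutation"
  attr(out, "iterations") <- iterations
  attr(out, "seed") <- seed
  out
}

#' Subsampling robustness test
#'
#' Draws `k` samples per condition without replacement, recomputes the
#' pooled-cell MWU p value per stratum on the retained samples, and
#' repeats.  If a condition has fewer than `k` samples, `k` is lowered
#' to the minimum group size with a warning.
#'
#' @inheritParams permutationTest
#' @param k samples drawn per condition (default 15).
#' @return as [permutationTest()], with `mode = "subsampling"` and
#'   attribute `k`.
#' @export
subsamplingTest <- function(scores, scoreNames = localScoreNames,
                            radius = 5L, cellTypes = NULL, k = 15L,
                            iterations = 100L, seed = 1L) {
  condOf <- sampleConditions(scores)
  conds <- sort(unique(condOf))
  sizes <- table(condOf)
  if (any(sizes < k)) {
    k <- min(sizes)
    warning("k lowered to the minimum condition group size: ", k)
  }
  pairs <- combn(conds, 2)
  strata <- localStrataData(scores, scoreNames, radius, cellTypes)
  pfuns <- lapply(strata, robustnessStratum, sampleCond = condOf, pairs = pairs)
  orig <- lapply(pfuns, function(f) f(condOf))
  key <- do.call(rbind, strsplit(names(strata), "\r", fixed = TRUE))
  origDf <- data.frame(
    score = rep(key[, 1], each = ncol(pairs)),
    cell_type = rep(key[, 2], each = ncol(pairs)),
    cond_a = rep(pairs[1, ], length(strata)),
    cond_b = rep(pairs[2, ], length(strata)),
    original_p = unlist(orig, use.names = FALSE), stringsAsFactors = FALSE)
  rows <- withSeed(seed, {
    lapply(seq_len(iterations), function(it) {
      keep <- unlist(lapply(conds, function(cc) {
        ids <- names(condOf)[condOf == cc]
        sample(ids, k)
      }), use.names = FALSE)
      sub <- condOf[keep]
      ps <- lapply(pfuns, function(f) f(sub))
      cbind(origDf[, c("score", "cell_type", "cond_a", "cond_b")],
            iteration = it, p = unlist(ps, use.names = FALSE))
    })
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(origDf[0, c("score", "cell_type", "cond_a", "cond_b")],
          iteration = integer(0), p = numeric(0))
  out <- merge(out, origDf, by = c("score", "cell_type", "cond_a", "cond_b"),
               sort = TRUE)
  out <- out[order(out$score, out$cell_type, out$cond_a, out$cond_b,
                   out$iteration), ]
  rownames(out) <- NULL
  attr(out, "original") <- origDf
  attr(out, "mode") <- "subsampling"
  attr(out, "iterations") <- iterations
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  out
}
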