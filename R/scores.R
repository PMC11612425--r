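#' Global normalized entropy of a spatial cell graph
#'
#' Shannon entropy of the cell-type fractions
#' \eqn{p_G(t) = |\{c \in V : \lambda(c) = t\}| / |V|}, normalized by
#' \eqn{\log |T|} where \eqn{T} is the full type universe:
#' \deqn{H(G) = -\log(|T|)^{-1} \sum_{t \in T} p_G(t) \log p_G(t).}
#' The convention \eqn{0 \log 0 = 0} applies, and \eqn{H(G) = 0} when
#' \eqn{|T| = 1} (no heterogeneity is representable).  Large values
#' indicate high overall cell-type heterogeneity.
#'
#' @param graph a [SpatialCellGraph-class] with labeled vertices.
#' @return a number in `[0, 1]`.
#' @export
globalEntropy <- function(graph) {
  stopifnot(is(graph, "SpatialCellGraph"))
  n <- length(graph@cellIds)
  if (n == 0) stop("cannot compute entropy of an empty graph")
  K <- length(graph@typeUniverse)
  if (K <= 1) return(0)
  p <- tabulate(match(graph@labels, graph@typeUniverse), nbins = K) / n
  p <- p[p > 0]
  -sum(p * log(p)) / log(K)
}

#' Global homophily of a spatial cell graph
#'
#' Fraction of edges whose two endpoints carry the same cell-type
#' label.  Large values indicate that cells tend to be adjacent to
#' cells of their own type (low heterogeneity).
#'
#' @inheritParams globalEntropy
#' @return a number in `[0, 1]`.
#' @export
globalHomophily <- function(graph) {
  stopifnot(is(graph, "SpatialCellGraph"))
  e <- graph@edges
  if (nrow(e) == 0)
    stop("global homophily is undefined for an edgeless graph")
  mean(graph@labels[e[, 1]] == graph@labels[e[, 2]])
}

#' Cell-level heterogeneity scores at one or more radii
#'
#' Computes, for every cell \eqn{c} and every requested hop radius
#' \eqn{r}: local normalized entropy (entropy of the type fractions
#' within \eqn{N_r(c)}, normalized by the full type-universe size),
#' local homophily (monochromatic fraction of the edges induced by
#' \eqn{N_r(c)}; missing when the induced edge set is empty), and
#' egophily (fraction of cells in \eqn{N_r(c)} sharing \eqn{c}'s own
#' type, strictly positive by self-inclusion).
#'
#' @param graph a [SpatialCellGraph-class].
#' @param radii vector of positive integer hop radii.
#' @return a list with numeric matrices `entropy`, `homophily`,
#'   `egophily` and integer matrix `size` (cells x radii, dimnames set).
#' @export
localScores <- function(graph, radii) {
  stopifnot(is(graph, "SpatialCellGraph"))
  radii <- as.integer(radii)
  if (any(is.na(radii)) || any(radii < 1))
    stop("radii must be positive integers")
  o <- order(radii)
  K <- length(graph@typeUniverse)
  res <- cpp_local_scores(length(graph@cellIds), graph@edges - 1L,
                          match(graph@labels, graph@typeUniverse) - 1L,
                          K, radii[o])
  dn <- list(graph@cellIds, as.character(radii[o]))
  for (nm in c("entropy", "homophily", "egophily", "size"))
    dimnames(res[[nm]]) <- dn
  # restore requested radius order
  back <- match(as.character(radii), dn[[2]])
  for (nm in c("entropy", "homophily", "egophily", "size"))
    res[[nm]] <- res[[nm]][, back, drop = FALSE]
  res
}

#' @rdname localScores
#' @param r a single positive integer radius.
#' @return `localEntropy`, `localHomophily` and `egophily` return a
#'   named numeric vector over cells (possibly with NA for
#'   `localHomophily` where the induced edge set is empty).
#' @export
localEntropy <- function(graph, r) localScores(graph, r)$entropy[, 1]

#' @rdname localScores
#' @export
localHomophily <- function(graph, r) localScores(graph, r)$homophily[, 1]

#' @rdname localScores
#' @export
egophily <- function(graph, r) localScores(graph, r)$egophily[, 1]

#' Default hop radii for local heterogeneity scores
#' @return the integer vector c(1, 2, 3, 4, 5, 10, 20, 50, 100, 500).
#' @export
defaultRadii <- function() c(1L, 2L, 3L, 4L, 5L, 10L, 20L, 50L, 100L, 500L)

#' Compute all heterogeneity scores for a cohort of samples
#'
#' Per-sample driver: builds the Delaunay spatial graph of each sample
#' and computes the two global scores plus the three local scores at
#' every requested radius.  The type universe is fixed across the whole
#' cohort before scoring (all labels observed in `cells`, including
#' `"unknown"`), so entropy normalization is comparable between
#' samples; it is recorded in the output attributes and can be
#' overridden.
#'
#' Samples that fail the graph preconditions (fewer than 3 cells,
#' collinear or duplicated centroids) are reported and skipped, never
#' silently dropped.
#'
#' @param cells cohort cell table (see [validateCellTable()]); all cells
#'   must carry a type label (missing labels become `"unknown"`).
#' @param radii positive integer radii, by default [defaultRadii()].
#' @param typeUniverse optional explicit label universe.
#' @param includeUnknown if `FALSE`, cells labeled `"unknown"` are
#'   dropped before graph construction (exposed as a filter; the default
#'   keeps them as labeled vertices).
#' @return a long-format score table: columns `sample_id`, `condition`,
#'   `cell_id`, `cell_type`, `score`, `radius`, `value`.  Global rows
#'   have `score` in `global_entropy`/`global_homophily`, `radius = NA`
#'   and `cell_id = NA`.  Attributes: `typeUniverse`, `radii`,
#'   `skipped` (named character vector of skipped samples and reasons).
#' @export
computeAllScores <- function(cells, radii = defaultRadii(),
                             typeUniverse = NULL, includeUnknown = TRUE) {
  cells <- validateCellTable(cells, fillUnknown = TRUE)
  if (!includeUnknown) cells <- cells[cells$cell_type != "unknown", , drop = FALSE]
  if (nrow(cells) == 0) stop("no cells to score")
  if (is.null(typeUniverse))
    typeUniverse <- sort(unique(cells$cell_type))
  radii <- sort(unique(as.integer(radii)))
  samples <- unique(cells$sample_id)
  skipped <- character(0)
  parts <- list()
  for (s in samples) {
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    g <- tryCatch(buildDelaunayGraph(sub, typeUniverse = typeUniverse),
                  error = function(e) e)
    if (inherits(g, "error")) {
      skipped[s] <- conditionMessage(g)
      next
    }
    loc <- localScores(g, radii)
    n <- nCells(g)
    cond <- as.character(sub$condition[1])
    globalDf <- data.frame(
      sample_id = s, condition = cond, cell_id = NA_character_,
      cell_type = NA_character_,
      score = c("global_entropy", "global_homophily"),
      radius = NA_integer_,
      value = c(globalEntropy(g), globalHomophily(g)),
      stringsAsFactors = FALSE)
    localDf <- data.frame(
      sample_id = s, condition = cond,
      cell_id = rep(rep(g@cellIds, length(radii)), 3L),
      cell_type = rep(rep(g@labels, length(radii)), 3L),
      score = rep(c("local_entropy", "local_homophily", "egophily"),
                  each = n * length(radii)),
      radius = rep(rep(radii, each = n), 3L),
      value = c(loc$entropy, loc$homophily, loc$egophily),
      stringsAsFactors = FALSE)
    parts[[s]] <- rbind(globalDf, localDf)
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " sample(s): ",
            paste(sprintf("%s (%s)", names(skipped), skipped), collapse = "; "))
  if (!length(parts)) stop("no sample could be scored")
  out <- do.call(rbind, parts)
  out <- out[order(out$sample_id, out$score, out$radius, out$cell_id,
                   method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "typeUniverse") <- typeUniverse
  attr(out, "radii") <- radii
  attr(out, "skipped") <- skipped
  out
}

#' Read or write a score table CSV
#'
#' The tidy CSV dialect has columns
#' `sample_id,condition,cell_id,cell_type,score,radius,value`, with the
#' sentinel `"global"` in `radius` and an empty `cell_id` for
#' sample-level rows.
#'
#' @param scores a score table as returned by [computeAllScores()].
#' @param path file path.
#' @export
writeScoreTable <- function(scores, path) {
  out <- scores
  out$radius <- ifelse(is.na(out$radius), "global", as.character(out$radius))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(radius = "character"))
  need <- c("sample_id", "condition", "cell_id", "cell_type",
            "score", "radius", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("score table '%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df$radius <- ifelse(df$radius == "global", NA, df$radius)
  df$radius <- as.integer(df$radius)
  df$cell_id[!is.na(df$cell_id) & df$cell_id == ""] <- NA
  df$cell_type[!is.na(df$cell_type) & df$cell_type == ""] <- NA
  df
}
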