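#' Spatial cell graph of one tissue sample
#'
#' An undirected graph whose vertices are segmented cells of a single
#' sample and whose edges connect spatially adjacent cells (by default,
#' Delaunay neighbors of the cell centroids).  Each vertex carries a
#' cell-type label drawn from a fixed type universe shared across the
#' cohort, so that entropy normalization is comparable between samples.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot coords numeric matrix with columns \code{x}, \code{y} (pixel
#'   units; x = column index, y = row index, 0-based pixel centers), or a
#'   0-row matrix for graphs without attached coordinates.
#' @slot edges 2-column integer matrix of vertex indices, one row per
#'   undirected edge, with \code{edges[, 1] < edges[, 2]}.
#' @slot labels character vector of cell-type labels, parallel to
#'   \code{cellIds}.
#' @slot typeUniverse ordered character vector of all labels used for
#'   normalization (a superset of the labels present in this sample).
#' @slot sampleId scalar sample identifier.
#' @slot condition scalar condition label of the sample (may be NA).
#'
#' @seealso [buildDelaunayGraph()], [spatialCellGraph()]
#' @export
setClass("SpatialCellGraph",
  representation(
    cellIds = "character",
    coords = "matrix",
    edges = "matrix",
    labels = "character",
    typeUniverse = "character",
    sampleId = "character",
    condition = "character"
  )
)

setValidity("SpatialCellGraph", function(object) {
  n <- length(object@cellIds)
  msg <- character()
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "cell ids must be unique")
  if (length(object@labels) != n)
    msg <- c(msg, "labels must be parallel to cellIds")
  if (!(nrow(object@coords) %in% c(0L, n)))
    msg <- c(msg, "coords must have one row per cell (or none)")
  e <- object@edges
  if (ncol(e) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0) {
    if (any(e < 1L | e > n))
      msg <- c(msg, "edge endpoints must be valid vertex indices")
    else {
      if (any(e[, 1] == e[, 2]))
        msg <- c(msg, "self loops are not allowed")
      if (any(e[, 1] > e[, 2]))
        msg <- c(msg, "edges must be stored with smaller index first")
      if (anyDuplicated(e))
        msg <- c(msg, "duplicate edges are not allowed")
    }
  }
  if (anyDuplicated(object@typeUniverse))
    msg <- c(msg, "typeUniverse must not contain duplicates")
  if (n > 0 && !all(object@labels %in% object@typeUniverse))
    msg <- c(msg, "every label must be contained in the type universe")
  if (length(object@sampleId) != 1L || length(object@condition) != 1L)
    msg <- c(msg, "sampleId and condition must be scalars")
  if (length(msg)) msg else TRUE
})

#' Cell-by-protein abundance matrix
#'
#' Fractional positivity values \eqn{A(c, p) \in [0, 1]}: for each cell
#' segment the fraction of its pixels that binarize positive in the
#' channel of protein \eqn{p}.  Binarization metadata (window size,
#' per-channel offsets, smoothing bandwidth) is stored alongside.
#'
#' @slot values numeric matrix, rows = cells (rownames are cell labels of
#'   the segmentation mask), columns = proteins.
#' @slot window odd integer window size used for adaptive binarization
#'   (NA if the matrix was not derived from images).
#' @slot offsets named numeric vector of per-channel offset constants.
#' @slot sigma Gaussian bandwidth (pixels) of the binarization window.
#'
#' @seealso [abundanceMatrix()], [adaptiveBinarize()]
#' @export
setClass("AbundanceMatrix",
  representation(
    values = "matrix",
    window = "integer",
    offsets = "numeric",
    sigma = "numeric"
  )
)

setValidity("AbundanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  else if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    msg <- c(msg, "abundance values must be finite and in [0, 1]")
  if (is.null(rownames(v))) msg <- c(msg, "values must have cell rownames")
  if (is.null(colnames(v))) msg <- c(msg, "values must have protein colnames")
  if (length(msg)) msg else TRUE
})

#' Reference expression table for rule-based cell typing
#'
#' Cluster-level expression values \eqn{X(C, g)} with cluster sizes and
#' cluster-to-cell-type annotations, together with the derived type-level
#' values \eqn{X(t, g)} obtained by size-weighted mean aggregation over
#' the clusters annotated with each type.
#'
#' @slot clusterExpr numeric matrix, rows = clusters, columns = genes.
#' @slot clusterSizes positive numeric vector of cluster cell counts.
#' @slot clusterTypes character vector of cell-type annotations, parallel
#'   to the clusters.
#' @slot typeExpr derived numeric matrix, rows = cell types, columns =
#'   genes.
#'
#' @seealso [referenceExpression()], [aggregateReference()],
#'   [readHPAReference()]
#' @export
setClass("ReferenceExpression",
  representation(
    clusterExpr = "matrix",
    clusterSizes = "numeric",
    clusterTypes = "character",
    typeExpr = "matrix"
  )
)

setValidity("ReferenceExpression", function(object) {
  msg <- character()
  nc <- nrow(object@clusterExpr)
  if (length(object@clusterSizes) != nc || length(object@clusterTypes) != nc)
    msg <- c(msg, "cluster sizes and types must be parallel to clusterExpr rows")
  if (any(object@clusterSizes <= 0))
    msg <- c(msg, "cluster sizes must be positive")
  if (any(is.na(object@clusterTypes)) || any(object@clusterTypes == ""))
    msg <- c(msg, "every cluster must be annotated with a cell type")
  if (!identical(colnames(object@clusterExpr), colnames(object@typeExpr)))
    msg <- c(msg, "typeExpr must share gene columns with clusterExpr")
  # aggregated values must lie within the range of their clusters
  for (t in rownames(object@typeExpr)) {
    rows <- object@clusterTypes == t
    if (!any(rows)) next
    sub <- object@clusterExpr[rows, , drop = FALSE]
    bad <- object@typeExpr[t, ] < apply(sub, 2, min) - 1e-8 |
      object@typeExpr[t, ] > apply(sub, 2, max) + 1e-8
    if (any(bad))
      msg <- c(msg, sprintf("aggregated values out of cluster range for type '%s'", t))
  }
  if (length(msg)) msg else TRUE
})
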