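#' Construct a SpatialCellGraph from an explicit edge list
#'
#' Low-level constructor, useful for building abstract labeled graphs
#' (paths, stars, externally supplied neighborhood graphs).  For graphs
#' derived from cell centroids use [buildDelaunayGraph()].
#'
#' @param cellIds character vector of unique cell identifiers.
#' @param edges 2-column matrix of edges: either integer vertex indices
#'   or character cell ids.  Edges are deduplicated and stored
#'   undirected; self loops are an error.
#' @param labels character vector of cell-type labels (parallel to
#'   `cellIds`); missing values become `"unknown"`.
#' @param coords optional numeric matrix of centroid coordinates with
#'   columns x, y.
#' @param typeUniverse ordered label universe used for entropy
#'   normalization; defaults to the sorted labels present (including
#'   `"unknown"` if it occurs).
#' @param sampleId,condition scalar sample metadata.
#' @return a [SpatialCellGraph-class] object.
#' @export
spatialCellGraph <- function(cellIds, edges, labels,
                             coords = NULL, typeUniverse = NULL,
                             sampleId = NA_character_,
                             condition = NA_character_) {
  cellIds <- as.character(cellIds)
  labels <- as.character(labels)
  labels[is.na(labels) | labels == ""] <- "unknown"
  if (is.character(edges)) {
    idx <- match(edges, cellIds)
    if (any(is.na(idx)))
      stop("edge endpoints not found among cellIds: ",
           paste(unique(edges[is.na(idx)]), collapse = ", "))
    edges <- matrix(idx, ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (is.null(coords)) {
    coords <- matrix(numeric(0), ncol = 2)
  } else {
    coords <- as.matrix(coords)
  }
  colnames(coords) <- c("x", "y")[seq_len(min(2, ncol(coords)))]
  if (is.null(typeUniverse))
    typeUniverse <- sort(unique(labels))
  new("SpatialCellGraph",
      cellIds = cellIds, coords = coords, edges = edges,
      labels = labels, typeUniverse = as.character(typeUniverse),
      sampleId = as.character(sampleId), condition = as.character(condition))
}

#' Build the Delaunay spatial graph of one sample
#'
#' Vertices are the cells of one sample; edges are exactly the edges of
#' the Delaunay triangulation of the centroid point set (deduplicated,
#' undirected, no pruning).  The triangulation of a finite point set is
#' connected, so the resulting graph is, too.  Cocircular point
#' configurations (e.g. the four corners of a square) admit several
#' valid triangulations; the implementation returns one of them
#' deterministically (insertion-order dependent diagonal).
#'
#' @param cells cell table rows of a single sample (see
#'   [validateCellTable()]), or any data.frame with columns `cell_id`,
#'   `x`, `y` (plus optional `sample_id`, `condition`, `cell_type`).
#' @param typeUniverse optional cohort-wide label universe (see
#'   [spatialCellGraph()]).
#' @return a [SpatialCellGraph-class] object.
#' @section Errors: fewer than 3 cells, an all-collinear point set, or
#'   duplicated coordinates are rejected with a diagnostic naming the
#'   offending cells.
#' @examples
#' cells <- data.frame(cell_id = c("a", "b", "c"),
#'                     x = c(0, 1, 0), y = c(0, 0, 1))
#' g <- buildDelaunayGraph(cells)
#' edgeMatrix(g)  # the three edges of the triangle
#' @export
buildDelaunayGraph <- function(cells, typeUniverse = NULL) {
  if ("sample_id" %in% names(cells) && length(unique(cells$sample_id)) > 1)
    stop("buildDelaunayGraph expects the cells of a single sample; got ",
         length(unique(cells$sample_id)), " samples")
  n <- nrow(cells)
  if (n < 3)
    stop("Delaunay triangulation needs at least 3 cells; got ", n,
         if (n > 0) paste0(" (", paste(cells$cell_id, collapse = ", "), ")") else "")
  dup <- duplicated(cells[, c("x", "y")]) |
    duplicated(cells[, c("x", "y")], fromLast = TRUE)
  if (any(dup))
    stop("duplicate centroid coordinates (upstream segmentation failure?): ",
         paste(utils::head(cells$cell_id[dup], 6), collapse = ", "))
  o <- orientationSpread(cells$x, cells$y)
  if (!o)
    stop("all cell centroids are collinear; cannot triangulate (cells ",
         paste(utils::head(cells$cell_id, 6), collapse = ", "), " ...)")
  edges <- cpp_delaunay_edges(as.numeric(cells$x), as.numeric(cells$y))
  spatialCellGraph(
    cellIds = cells$cell_id,
    edges = edges,
    labels = if ("cell_type" %in% names(cells)) cells$cell_type
             else rep("unknown", n),
    coords = cbind(x = as.numeric(cells$x), y = as.numeric(cells$y)),
    typeUniverse = typeUniverse,
    sampleId = if ("sample_id" %in% names(cells)) as.character(cells$sample_id[1]) else NA_character_,
    condition = if ("condition" %in% names(cells)) as.character(cells$condition[1]) else NA_character_)
}

# TRUE iff the point set spans two dimensions
orientationSpread <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  o <- (x[2] - x[1]) * (y - y[1]) - (y[2] - y[1]) * (x - x[1])
  any(o != 0)
}

## ------------------------------------------------------------------ methods

#' @rdname accessors
#' @export
setMethod("cellIds", "SpatialCellGraph", function(x, ...) x@cellIds)

#' @rdname accessors
#' @export
setMethod("cellTypes", "SpatialCellGraph",
          function(x, ...) setNames(x@labels, x@cellIds))

#' @rdname accessors
#' @export
setMethod("typeUniverse", "SpatialCellGraph", function(x, ...) x@typeUniverse)

#' @rdname accessors
#' @export
setMethod("edgeMatrix", "SpatialCellGraph", function(x, ...) x@edges)

#' @rdname accessors
#' @export
setMethod("cellCoords", "SpatialCellGraph", function(x, ...) {
  co <- x@coords
  if (nrow(co)) rownames(co) <- x@cellIds
  co
})

#' @rdname accessors
#' @export
setMethod("sampleId", "SpatialCellGraph", function(x, ...) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleCondition", "SpatialCellGraph", function(x, ...) x@condition)

#' @rdname accessors
#' @export
setMethod("nCells", "SpatialCellGraph", function(x, ...) length(x@cellIds))

#' @export
setMethod("asIgraph", "SpatialCellGraph", function(x) {
  g <- igraph::make_empty_graph(n = length(x@cellIds), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = x@cellIds)
  g <- igraph::set_vertex_attr(g, "cell_type", value = x@labels)
  if (nrow(x@edges))
    g <- igraph::add_edges(g, t(x@edges))
  g
})

setMethod("show", "SpatialCellGraph", function(object) {
  cat(sprintf("SpatialCellGraph: %d cells, %d edges\n",
              length(object@cellIds), nrow(object@edges)))
  cat(sprintf("  sample: %s (condition: %s)\n",
              object@sampleId, object@condition))
  tab <- table(factor(object@labels, levels = object@typeUniverse))
  cat(sprintf("  type universe (|T| = %d): %s\n", length(object@typeUniverse),
              paste(sprintf("%s(%d)", names(tab), tab), collapse = ", ")))
})

#' Write a graph as edge-list and node-attribute CSVs
#'
#' @param graph a [SpatialCellGraph-class].
#' @param prefix output path prefix; writes `<prefix>_edges.csv`
#'   (columns source,target as cell ids) and `<prefix>_nodes.csv`
#'   (cell_id,x,y,cell_type).
#' @return the two paths, invisibly.
#' @export
writeGraph <- function(graph, prefix) {
  e <- graph@edges
  edgeDf <- data.frame(source = graph@cellIds[e[, 1]],
                       target = graph@cellIds[e[, 2]])
  co <- if (nrow(graph@coords)) graph@coords else
    matrix(NA_real_, nrow = length(graph@cellIds), ncol = 2)
  nodeDf <- data.frame(cell_id = graph@cellIds,
                       x = co[, 1], y = co[, 2],
                       cell_type = graph@labels)
  pe <- paste0(prefix, "_edges.csv")
  pn <- paste0(prefix, "_nodes.csv")
  write.csv(edgeDf, pe, row.names = FALSE)
  write.csv(nodeDf, pn, row.names = FALSE)
  invisible(c(edges = pe, nodes = pn))
}
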