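#' @name accessors
#' @title Accessors for spatialhet S4 objects
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The corresponding component: cell ids, labels, the type
#'   universe, the edge matrix, centroid coordinates, or scalar sample
#'   metadata.
NULL

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x, ...) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("typeUniverse", function(x, ...) standardGeneric("typeUniverse"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x, ...) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("cellCoords", function(x, ...) standardGeneric("cellCoords"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x, ...) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("sampleCondition", function(x, ...) standardGeneric("sampleCondition"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x, ...) standardGeneric("nCells"))

#' Convert a spatialhet object to an igraph graph
#'
#' @param x a [SpatialCellGraph-class] object.
#' @return an [igraph::igraph] object with vertex attributes `name`
#'   (cell id) and `cell_type`.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("abundanceValues", function(x, ...) standardGeneric("abundanceValues"))

#' @rdname accessors
#' @export
setGeneric("typeExpression", function(x, ...) standardGeneric("typeExpression"))

#' @rdname accessors
#' @export
setGeneric("referenceGenes", function(x, ...) standardGeneric("referenceGenes"))

#' @rdname accessors
#' @export
setGeneric("referenceTypes", function(x, ...) standardGeneric("referenceTypes"))
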