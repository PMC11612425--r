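#' r-hop neighborhood of a cell
#'
#' The r-hop neighborhood \eqn{N_r(c)} of a cell \eqn{c} contains every
#' cell whose unweighted shortest-path (hop) distance from \eqn{c} is at
#' most \eqn{r}, including \eqn{c} itself.  The induced edge set
#' \eqn{E_{N_r(c)}} contains the parent-graph edges with both endpoints
#' inside the neighborhood.  On externally supplied disconnected graphs,
#' vertices unreachable from the center are outside every finite-radius
#' neighborhood.
#'
#' @param graph a [SpatialCellGraph-class].
#' @param center cell id of the neighborhood center.
#' @param r non-negative integer hop radius; `r = 0` yields the
#'   singleton neighborhood with no induced edges.
#' @return a list of class `Neighborhood` with elements `center`,
#'   `radius`, `members` (character cell ids, sorted) and
#'   `inducedEdges` (2-column character matrix of cell ids).
#' @export
khopNeighborhood <- function(graph, center, r) {
  stopifnot(is(graph, "SpatialCellGraph"))
  if (length(center) != 1 || !center %in% graph@cellIds)
    stop("unknown center cell: ", center)
  r <- as.integer(r)
  if (is.na(r) || r < 0) stop("radius r must be a non-negative integer")
  if (r == 0L) {
    members <- as.character(center)
  } else {
    ig <- asIgraph(graph)
    members <- names(igraph::ego(ig, order = r, nodes = center)[[1]])
  }
  newNeighborhood(graph, center, r, members)
}

newNeighborhood <- function(graph, center, r, members) {
  members <- sort(members)
  if (r > 0 && nrow(graph@edges)) {
    ids <- graph@cellIds
    keep <- ids[graph@edges[, 1]] %in% members & ids[graph@edges[, 2]] %in% members
    induced <- cbind(ids[graph@edges[keep, 1]], ids[graph@edges[keep, 2]])
  } else {
    induced <- matrix(character(0), ncol = 2)
  }
  structure(list(center = as.character(center), radius = r,
                 members = members, inducedEdges = induced),
            class = "Neighborhood")
}

#' @export
print.Neighborhood <- function(x, ...) {
  cat(sprintf("Neighborhood: center %s, r = %d, %d members, %d induced edges\n",
              x$center, x$radius, length(x$members), nrow(x$inducedEdges)))
  invisible(x)
}

#' All r-hop neighborhoods of a graph
#'
#' Batch form of [khopNeighborhood()]: one bounded-distance breadth-first
#' sweep per vertex in compiled code, returning the identical
#' neighborhoods as per-vertex calls.
#'
#' @inheritParams khopNeighborhood
#' @return named list of `Neighborhood` objects, one per cell.
#' @export
allKhopNeighborhoods <- function(graph, r) {
  stopifnot(is(graph, "SpatialCellGraph"))
  r <- as.integer(r)
  if (is.na(r) || r < 0) stop("radius r must be a non-negative integer")
  n <- length(graph@cellIds)
  mem <- cpp_khop_members(n, graph@edges - 1L, r)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- newNeighborhood(graph, graph@cellIds[i], r,
                                graph@cellIds[mem[[i]]])
  }
  names(out) <- graph@cellIds
  out
}
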