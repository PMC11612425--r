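#' Aggregate cluster-level reference expression to cell-type level
#'
#' Size-weighted mean over the clusters annotated with each cell type:
#' \deqn{X(t, g) = \left(\sum_{C: \sigma(C) = t} |C|\right)^{-1}
#'       \sum_{C: \sigma(C) = t} |C| \cdot X(C, g).}
#'
#' @param clusterExpr numeric matrix, rows = clusters, columns = genes.
#' @param clusterSizes positive cluster cell counts (parallel to rows).
#' @param clusterTypes cell-type annotation per cluster.
#' @return numeric matrix, rows = cell types (sorted), columns = genes.
#' @export
aggregateReference <- function(clusterExpr, clusterSizes, clusterTypes) {
  clusterExpr <- as.matrix(clusterExpr)
  if (length(clusterSizes) != nrow(clusterExpr) ||
      length(clusterTypes) != nrow(clusterExpr))
    stop("clusterSizes and clusterTypes must be parallel to clusterExpr rows")
  if (any(clusterSizes <= 0)) stop("cluster sizes must be positive")
  types <- sort(unique(as.character(clusterTypes)))
  out <- matrix(NA_real_, nrow = length(types), ncol = ncol(clusterExpr),
                dimnames = list(types, colnames(clusterExpr)))
  for (t in types) {
    rows <- clusterTypes == t
    w <- clusterSizes[rows]
    tot <- sum(w)
    if (tot <= 0) stop("zero total cluster size for type ", t)
    out[t, ] <- colSums(clusterExpr[rows, , drop = FALSE] * w) / tot
  }
  out
}

#' Construct a ReferenceExpression object
#'
#' @inheritParams aggregateReference
#' @param clusterIds optional cluster identifiers (rownames).
#' @return a [ReferenceExpression-class] with the derived type-level
#'   matrix.
#' @export
referenceExpression <- function(clusterExpr, clusterSizes, clusterTypes,
                                clusterIds = NULL) {
  clusterExpr <- as.matrix(clusterExpr)
  if (!is.null(clusterIds)) rownames(clusterExpr) <- clusterIds
  if (is.null(colnames(clusterExpr)))
    stop("clusterExpr must have gene column names")
  typeExpr <- aggregateReference(clusterExpr, clusterSizes, clusterTypes)
  new("ReferenceExpression", clusterExpr = clusterExpr,
      clusterSizes = as.numeric(clusterSizes),
      clusterTypes = as.character(clusterTypes), typeExpr = typeExpr)
}

#' @rdname accessors
#' @export
setMethod("typeExpression", "ReferenceExpression", function(x, ...) x@typeExpr)

#' @rdname accessors
#' @export
setMethod("referenceGenes", "ReferenceExpression",
          function(x, ...) colnames(x@typeExpr))

#' @rdname accessors
#' @export
setMethod("referenceTypes", "ReferenceExpression",
          function(x, ...) rownames(x@typeExpr))

setMethod("show", "ReferenceExpression", function(object) {
  cat(sprintf("ReferenceExpression: %d clusters, %d cell types, %d genes\n",
              nrow(object@clusterExpr), nrow(object@typeExpr),
              ncol(object@typeExpr)))
})

#' Read an HPA-style single-cell reference
#'
#' Parses the tab-separated dialect of the Human Protein Atlas
#' single-cell files: an expression table with columns `Tissue`,
#' `Cluster`, `Gene name` and a value column (default `nTPM`), and a
#' cluster description table with columns `Tissue`, `Cluster`,
#' `Cell type` and `Cell count`.  Column matching is case-insensitive
#' and tolerant of the space/underscore difference.
#'
#' @param exprFile path to the cluster x gene expression TSV.
#' @param clusterFile path to the cluster description TSV.
#' @param tissue optional tissue name to filter both tables on.
#' @param valueColumn name of the expression value column.
#' @return a [ReferenceExpression-class].
#' @export
readHPAReference <- function(exprFile, clusterFile, tissue = NULL,
                             valueColumn = "nTPM") {
  norm <- function(x) gsub("[ _.]", "", tolower(x))
  findCol <- function(df, name, file) {
    i <- match(norm(name), norm(names(df)))
    if (is.na(i))
      stop(sprintf("'%s': missing required column '%s'", file, name),
           call. = FALSE)
    df[[i]]
  }
  ex <- read.delim(exprFile, stringsAsFactors = FALSE, check.names = FALSE)
  cl <- read.delim(clusterFile, stringsAsFactors = FALSE, check.names = FALSE)
  exTissue <- findCol(ex, "Tissue", exprFile)
  exCluster <- as.character(findCol(ex, "Cluster", exprFile))
  exGene <- findCol(ex, "Gene name", exprFile)
  exValue <- as.numeric(findCol(ex, valueColumn, exprFile))
  clTissue <- findCol(cl, "Tissue", clusterFile)
  clCluster <- as.character(findCol(cl, "Cluster", clusterFile))
  clType <- findCol(cl, "Cell type", clusterFile)
  clCount <- as.numeric(findCol(cl, "Cell count", clusterFile))
  if (!is.null(tissue)) {
    keep <- tolower(exTissue) == tolower(tissue)
    exCluster <- exCluster[keep]; exGene <- exGene[keep]; exValue <- exValue[keep]
    keep <- tolower(clTissue) == tolower(tissue)
    clCluster <- clCluster[keep]; clType <- clType[keep]; clCount <- clCount[keep]
  }
  genes <- sort(unique(exGene))
  clusters <- sort(unique(exCluster))
  m <- matrix(0, nrow = length(clusters), ncol = length(genes),
              dimnames = list(clusters, genes))
  m[cbind(match(exCluster, clusters), match(exGene, genes))] <- exValue
  idx <- match(clusters, clCluster)
  if (any(is.na(idx)))
    stop("clusters missing from the description table: ",
         paste(clusters[is.na(idx)], collapse = ", "))
  referenceExpression(m, clCount[idx], clType[idx], clusterIds = clusters)
}

#' Marker-specificity spread scores
#'
#' For every remaining cell type t and gene g,
#' \deqn{s(t, g) = X(t, g) - \max\{X(t', g) : t' \in \Sigma
#'       \setminus \{t\}\},}
#' the margin by which g's reference expression in t exceeds its
#' maximum in any other remaining type.  Genes with large spread are
#' candidate markers for t.  Requires at least two remaining types.
#'
#' @param reference a [ReferenceExpression-class] or a type x gene
#'   matrix.
#' @param types subset of remaining cell types (default: all).
#' @return numeric matrix of spread scores, rows = `types`.
#' @export
spreadScores <- function(reference, types = NULL) {
  X <- if (is(reference, "ReferenceExpression")) reference@typeExpr
       else as.matrix(reference)
  if (is.null(types)) types <- rownames(X)
  if (length(types) < 2)
    stop("spread scores need at least two remaining cell types")
  X <- X[types, , drop = FALSE]
  s <- X
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    top <- which.max(col)
    mx <- col[top]
    mx2 <- if (length(col) > 1) max(col[-top]) else -Inf
    s[, j] <- col - mx
    s[top, j] <- mx - mx2
  }
  s
}

#' Two-component Gaussian mixture fit with a bimodality gate
#'
#' Fits a two-component, unequal-variance Gaussian mixture to a vector
#' of per-cell abundances (model-based EM via mclust, deterministic
#' hierarchical initialization; any internal subsampling is seeded).
#' Components are ordered so that \eqn{\mu_0 \le \mu_1}.  The gene is
#' flagged "good" iff the two modes are separated:
#' \deqn{\mu_0 + z \sigma_0 < \mu_1 - z \sigma_1,}
#' with \eqn{z = 1.96} by default.  Fits with a collapsed component
#' (sd below 1e-6) or too few observations are never good.
#'
#' @param values numeric vector of abundances in `[0, 1]`.
#' @param seed optional seed for the fit.
#' @param minPerComponent minimum observations per component required
#'   to attempt a fit (the vector must have at least twice this many).
#' @param z separation multiplier.
#' @return a list with `mu0`, `sigma0`, `mu1`, `sigma1`, `good`, `n`
#'   and `reason` (why the gene is not good, if applicable).
#' @export
fitBimodal <- function(values, seed = NULL, minPerComponent = 5L, z = 1.96) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  out <- list(mu0 = NA_real_, sigma0 = NA_real_, mu1 = NA_real_,
              sigma1 = NA_real_, good = FALSE, n = length(values),
              reason = "")
  if (length(values) < 2L * minPerComponent) {
    out$reason <- "too few observations"
    return(out)
  }
  if (length(unique(values)) <= 2L) {
    # (near-)constant data: any two-component fit collapses, and the
    # EM machinery is not guaranteed to terminate on such input
    out$reason <- "degenerate component (sd collapse)"
    return(out)
  }
  mclustBIC <- mclust::mclustBIC  # Mclust()/me() resolve these in the caller
  meV <- mclust::meV
  # best of: deterministic hierarchical initialization plus seeded
  # k-means-initialized EM restarts (guards against local optima that
  # split a wide mode instead of separating the two modes)
  fits <- withSeed(seed, {
    cand <- list(tryCatch(
      suppressWarnings(mclust::Mclust(values, G = 2, modelNames = "V",
                                      verbose = FALSE)),
      error = function(e) NULL))
    for (r in seq_len(10)) {
      cand[[r + 1]] <- tryCatch({
        km <- suppressWarnings(stats::kmeans(values, centers = 2,
                                             nstart = 1, iter.max = 20))
        zInit <- cbind(km$cluster == 1, km$cluster == 2) * 1
        suppressWarnings(mclust::me(data = values, modelName = "V", z = zInit))
      }, error = function(e) NULL)
    }
    cand
  })
  ll <- vapply(fits, function(f) {
    if (is.null(f) || is.null(f$parameters) || is.null(f$loglik) ||
        length(f$parameters$mean) != 2L ||
        !(length(f$parameters$variance$sigmasq) %in% c(1L, 2L)) ||
        any(!is.finite(as.numeric(f$parameters$mean))) ||
        any(!is.finite(as.numeric(f$parameters$variance$sigmasq))))
      -Inf else {
      l <- as.numeric(f$loglik)[1]
      if (is.finite(l)) l else -Inf
    }
  }, numeric(1))
  if (all(ll == -Inf)) {
    out$reason <- "mixture fit failed"
    return(out)
  }
  fit <- fits[[which.max(ll)]]
  mu <- as.numeric(fit$parameters$mean)
  sg <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sg) == 1L) sg <- rep(sg, 2L)
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]
  out$mu0 <- mu[1]; out$sigma0 <- sg[1]
  out$mu1 <- mu[2]; out$sigma1 <- sg[2]
  if (any(sg < 1e-6)) {
    out$reason <- "degenerate component (sd collapse)"
    return(out)
  }
  out$good <- isWellSeparated(mu[1], sg[1], mu[2], sg[2], z = z)
  if (!out$good) out$reason <- "modes not separated"
  out
}

#' Bimodal separation condition
#'
#' @param mu0,sigma0 mean and sd of the lower mode.
#' @param mu1,sigma1 mean and sd of the upper mode.
#' @param z separation multiplier (default 1.96).
#' @return `TRUE` iff `mu0 + z*sigma0 < mu1 - z*sigma1`.
#' @export
isWellSeparated <- function(mu0, sigma0, mu1, sigma1, z = 1.96) {
  mu0 + z * sigma0 < mu1 - z * sigma1
}

#' Iterative rule-based cell-type assignment
#'
#' Assigns cell types to cells from their protein abundances, guided by
#' a reference expression table.  Each iteration: (1) spread scores
#' s(t, g) are recomputed over the remaining types and sorted into a
#' descending candidate list L (ties broken by type then gene name);
#' (2) a two-component Gaussian mixture is fitted per gene over the
#' not-yet-assigned cells, and genes passing the separation gate are
#' "good"; (3) the first pair (t*, g*) in L with a good g* is taken,
#' and every unassigned cell with abundance strictly above
#' `mu1(g*) - z*sigma1(g*)` is assigned type t*; (4) t* is removed
#' from the remaining types and the assigned cells from the pool.  The
#' protocol stops when no cells remain, no types remain, fewer than two
#' types remain (the spread is then undefined), or no gene is good;
#' remaining cells are labeled `"unknown"`.
#'
#' Cells are sorted by id before fitting, so the result does not depend
#' on input order.
#'
#' @param abundance an [AbundanceMatrix-class] or a cell x protein
#'   matrix with rownames.
#' @param reference a [ReferenceExpression-class].
#' @param geneMap optional data.frame with columns `protein`, `gene`
#'   mapping measured protein names to reference gene symbols
#'   (case-insensitive exact match; defaults to the identity mapping).
#'   Unmatched proteins are dropped with a warning.
#' @param z separation/threshold multiplier (default 1.96).
#' @param seed base seed for the mixture fits.
#' @param minPerComponent passed to [fitBimodal()].
#' @return a list with `labels` (named character vector, one label per
#'   input cell, in input order), `log` (data.frame audit log with one
#'   row per iteration: type, gene, spread, mixture parameters, the
#'   threshold actually applied and the number of cells assigned) and
#'   `stopReason`.
#' @export
assignCellTypes <- function(abundance, reference, geneMap = NULL,
                            z = 1.96, seed = 0L, minPerComponent = 5L) {
  A <- if (is(abundance, "AbundanceMatrix")) abundance@values
       else as.matrix(abundance)
  if (is.null(rownames(A))) stop("abundance matrix must have cell rownames")
  if (!is(reference, "ReferenceExpression"))
    stop("reference must be a ReferenceExpression object")
  # map proteins to genes
  proteins <- colnames(A)
  if (is.null(geneMap)) {
    genes <- proteins
  } else {
    if (!all(c("protein", "gene") %in% names(geneMap)))
      stop("geneMap must have columns 'protein' and 'gene'")
    idx <- match(tolower(proteins), tolower(geneMap$protein))
    genes <- as.character(geneMap$gene[idx])
    genes[is.na(idx)] <- NA
  }
  refGenes <- referenceGenes(reference)
  gi <- match(tolower(genes), tolower(refGenes))
  drop <- is.na(gi)
  if (any(drop))
    warning("dropping protein(s) without a reference gene match: ",
            paste(proteins[drop], collapse = ", "))
  if (all(drop))
    stop("no overlap between measured proteins and reference genes")
  A <- A[, !drop, drop = FALSE]
  colnames(A) <- refGenes[gi[!drop]]

  Sigma <- referenceTypes(reference)
  X <- typeExpression(reference)[, colnames(A), drop = FALSE]
  origOrder <- rownames(A)
  A <- A[order(rownames(A)), , drop = FALSE]   # canonical data order
  pool <- rownames(A)
  labels <- setNames(rep(NA_character_, length(pool)), pool)
  logRows <- list()
  iter <- 0L
  stopReason <- NULL
  while (TRUE) {
    if (!length(pool)) { stopReason <- "all cells assigned"; break }
    if (!length(Sigma)) { stopReason <- "no cell types left"; break }
    if (length(Sigma) < 2L) {
      stopReason <- sprintf(
        "single remaining type '%s': spread score undefined, stopping",
        Sigma)
      break
    }
    iter <- iter + 1L
    s <- spreadScores(X, Sigma)
    cand <- data.frame(type = rep(rownames(s), ncol(s)),
                       gene = rep(colnames(s), each = nrow(s)),
                       spread = as.vector(s), stringsAsFactors = FALSE)
    cand <- cand[order(-cand$spread, cand$type, cand$gene, method = "radix"), ]
    fits <- list()
    pick <- NULL
    for (k in seq_len(nrow(cand))) {
      g <- cand$gene[k]
      if (is.null(fits[[g]]))
        fits[[g]] <- fitBimodal(A[pool, g], seed = childSeed(seed, iter, g),
                                minPerComponent = minPerComponent, z = z)
      if (fits[[g]]$good) { pick <- k; break }
    }
    if (is.null(pick)) { stopReason <- "no good genes"; break }
    tStar <- cand$type[pick]
    gStar <- cand$gene[pick]
    fit <- fits[[gStar]]
    threshold <- fit$mu1 - z * fit$sigma1
    assigned <- pool[A[pool, gStar] > threshold]
    labels[assigned] <- tStar
    logRows[[iter]] <- data.frame(
      iteration = iter, cell_type = tStar, gene = gStar,
      spread = cand$spread[pick], mu0 = fit$mu0, sigma0 = fit$sigma0,
      mu1 = fit$mu1, sigma1 = fit$sigma1, threshold = threshold,
      n_assigned = length(assigned),
      n_remaining = length(pool) - length(assigned),
      stringsAsFactors = FALSE)
    pool <- setdiff(pool, assigned)
    Sigma <- setdiff(Sigma, tStar)
  }
  labels[is.na(labels)] <- "unknown"
  log <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(iteration = integer(0), cell_type = character(0),
               gene = character(0), spread = numeric(0), mu0 = numeric(0),
               sigma0 = numeric(0), mu1 = numeric(0), sigma1 = numeric(0),
               threshold = numeric(0), n_assigned = integer(0),
               n_remaining = integer(0))
  list(labels = labels[origOrder], log = log, stopReason = stopReason)
}
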