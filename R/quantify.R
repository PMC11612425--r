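#' Adaptive binarization of an intensity channel
#'
#' Each pixel is set to 1 iff its intensity strictly exceeds the
#' Gaussian-weighted mean of its window neighborhood plus an offset
#' constant.  By default the offset is recomputed per channel as the
#' standard deviation of all intensities of that channel, which makes
#' the binarization robust to channel-specific intensity levels and
#' region-specific illumination.  Borders are handled by symmetric
#' reflection.
#'
#' The Gaussian bandwidth defaults to `0.3 * ((window - 1) / 2 - 1) +
#' 0.8` pixels, the common convention of a bandwidth proportional to
#' the window size; it can be overridden via `sigma`.
#'
#' @param channel numeric matrix of pixel intensities (rows = y, cols =
#'   x).
#' @param window odd integer window size (default 201).
#' @param offset offset constant added to the local mean; default
#'   `sd(channel)`.  A constant-valued channel therefore binarizes to
#'   all zeros (sd = 0 and the strict inequality fails at equality).
#' @param sigma Gaussian bandwidth in pixels.
#' @return integer matrix of 0/1 values, same shape as `channel`.
#' @export
adaptiveBinarize <- function(channel, window = 201L, offset = NULL,
                             sigma = NULL) {
  channel <- as.matrix(channel)
  storage.mode(channel) <- "double"
  if (any(!is.finite(channel))) stop("channel contains non-finite values")
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3; got ", window)
  if (is.null(sigma)) sigma <- 0.3 * ((window - 1) / 2 - 1) + 0.8
  if (is.null(offset)) offset <- stats::sd(as.vector(channel))
  # center intensities before smoothing: mathematically neutral (the
  # comparison is shift-invariant), but it makes the constant-image
  # case exact -- a constant channel binarizes to all zeros
  out <- cpp_adaptive_binarize(channel - mean(channel), window, sigma, offset)
  attr(out, "window") <- window
  attr(out, "offset") <- offset
  attr(out, "sigma") <- sigma
  out
}

# equivalent-area radius of labeled segments: sqrt(area / pi)
equivalentRadius <- function(areas) sqrt(areas / pi)

#' Complete missing cell membranes around orphan nuclei
#'
#' Cells whose membrane was detected are kept verbatim.  For every
#' nucleus without a detected cell (an "orphan"), a disc is drawn
#' around the nucleus centroid with radius `rho * r_nucleus`, where
#' `rho` is the mean ratio of cell to nucleus equivalent-area radius
#' over the matched nucleus/cell pairs, and `r_nucleus` is the orphan
#' nucleus' equivalent-area radius (`sqrt(area / pi)`).  Disc pixels
#' already claimed by a detected cell are not overwritten; pixels
#' contested by two or more new discs are assigned to the nucleus with
#' the nearer centroid (exact ties go to the lower nucleus label).  The
#' output segmentation is pairwise disjoint with one segment per
#' detected cell plus one per orphan nucleus.
#'
#' @param nuclei integer label matrix of nucleus segments (0 =
#'   background).
#' @param cells integer label matrix of detected cell segments, same
#'   shape.
#' @return a list with elements `mask` (completed integer label
#'   matrix), `rho` (the radius ratio used), `mapping` (data.frame
#'   `nucleus_label`, `cell_label`, `orphan`), and `tied` (number of
#'   contested pixels resolved by the label tie-break).
#' @section Errors: a nucleus overlapping two or more detected cells,
#'   a detected cell containing two or more nuclei, or the absence of
#'   any matched nucleus/cell pair is an error.
#' @export
completeMembranes <- function(nuclei, cells) {
  nuclei <- as.matrix(nuclei)
  cells <- as.matrix(cells)
  if (!identical(dim(nuclei), dim(cells)))
    stop("nucleus and cell masks must have the same shape")
  storage.mode(nuclei) <- "integer"
  storage.mode(cells) <- "integer"

  nIdx <- which(nuclei > 0L)
  if (!length(nIdx)) stop("nucleus mask is empty")
  nLab <- nuclei[nIdx]
  cLab <- cells[nIdx]
  pairs <- unique(data.frame(nucleus = nLab, cell = cLab))
  overlapped <- pairs[pairs$cell > 0L, , drop = FALSE]
  multi <- names(which(table(overlapped$nucleus) > 1))
  if (length(multi)) {
    bad <- overlapped[overlapped$nucleus %in% as.integer(multi), ]
    stop("nucleus overlapping two or more detected cells: ",
         paste(sprintf("nucleus %s -> cells {%s}", unique(bad$nucleus),
                       paste(bad$cell[bad$nucleus == bad$nucleus[1]],
                             collapse = ", ")), collapse = "; "))
  }
  multiCell <- names(which(table(overlapped$cell) > 1))
  if (length(multiCell))
    stop("detected cell containing two or more nuclei: cell(s) ",
         paste(multiCell, collapse = ", "))

  nucLabels <- sort(unique(nLab))
  matched <- overlapped[match(nucLabels, overlapped$nucleus), "cell"]
  names(matched) <- nucLabels
  orphans <- nucLabels[is.na(matched)]
  matchedNuc <- nucLabels[!is.na(matched)]
  if (!length(matchedNuc))
    stop("no nucleus with a detected cell; radius ratio is undefined")

  nucArea <- table(factor(nLab, levels = nucLabels))
  cellAll <- cells[cells > 0L]
  cellArea <- table(cellAll)
  rho <- mean(equivalentRadius(as.numeric(cellArea[as.character(matched[as.character(matchedNuc)])])) /
              equivalentRadius(as.numeric(nucArea[as.character(matchedNuc)])))

  out <- cells
  nr <- nrow(nuclei)
  tied <- 0L
  mapping <- data.frame(nucleus_label = nucLabels,
                        cell_label = as.integer(matched),
                        orphan = is.na(matched))
  if (length(orphans)) {
    usedLabels <- unique(cellAll)
    nextLabel <- max(c(usedLabels, nucLabels)) + 1L
    # orphan centroids and radii
    rows <- ((nIdx - 1L) %% nr) + 1L
    cols <- ((nIdx - 1L) %/% nr) + 1L
    bestD2 <- matrix(Inf, nrow = nr, ncol = ncol(nuclei))
    claim <- matrix(0L, nrow = nr, ncol = ncol(nuclei))
    for (k in seq_along(orphans)) {
      ok <- orphans[k]
      sel <- nLab == ok
      cy <- mean(rows[sel])
      cx <- mean(cols[sel])
      rad <- rho * equivalentRadius(as.numeric(nucArea[as.character(ok)]))
      r0 <- max(1L, floor(cy - rad)); r1 <- min(nr, ceiling(cy + rad))
      c0 <- max(1L, floor(cx - rad)); c1 <- min(ncol(nuclei), ceiling(cx + rad))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
      inside <- d2 <= rad^2
      sub <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
      insideIdx <- which(inside)
      for (ii in insideIdx) {
        rI <- sub[ii, 1]; cI <- sub[ii, 2]
        if (out[rI, cI] > 0L) next          # existing segments win
        dd <- d2[ii]
        if (dd < bestD2[rI, cI]) {
          bestD2[rI, cI] <- dd
          claim[rI, cI] <- ok
        } else if (dd == bestD2[rI, cI] && claim[rI, cI] > 0L) {
          tied <- tied + 1L                  # lower label wins: keep earlier
        }
      }
    }
    labelOf <- setNames(rep(NA_integer_, length(orphans)), orphans)
    for (ok in orphans) {
      labelOf[as.character(ok)] <- if (!(ok %in% usedLabels)) ok else {
        lb <- nextLabel
        nextLabel <- nextLabel + 1L
        lb
      }
    }
    sel <- claim > 0L
    out[sel] <- labelOf[as.character(claim[sel])]
    mapping$cell_label[mapping$orphan] <- labelOf[as.character(orphans)]
  }
  if (tied)
    message("completeMembranes: ", tied,
            " contested pixel(s) resolved by the lower-label tie-break")
  list(mask = out, rho = rho, mapping = mapping, tied = tied)
}

#' Protein abundance matrix from binarized channels and a segmentation
#'
#' Sets the abundance \eqn{A(c, p)} of protein \eqn{p} in cell \eqn{c}
#' to the fraction of positive binarized pixels within the segment of
#' \eqn{c}.
#'
#' @param binaryChannels named list of 0/1 matrices (one per protein),
#'   all sharing the segmentation's shape.
#' @param segmentation integer label matrix (0 = background).
#' @param window,offsets,sigma optional binarization metadata to record.
#' @return an [AbundanceMatrix-class]; rownames are the segment labels.
#' @export
abundanceMatrix <- function(binaryChannels, segmentation,
                            window = NA_integer_, offsets = NULL,
                            sigma = NA_real_) {
  segmentation <- as.matrix(segmentation)
  storage.mode(segmentation) <- "integer"
  if (is.null(names(binaryChannels)) || any(names(binaryChannels) == ""))
    stop("binaryChannels must be a named list (one name per protein)")
  labels <- sort(unique(segmentation[segmentation > 0L]))
  if (!length(labels)) stop("segmentation has no labeled segments")
  inside <- segmentation > 0L
  segVec <- factor(segmentation[inside], levels = labels)
  areas <- as.numeric(table(segVec))
  vals <- matrix(NA_real_, nrow = length(labels), ncol = length(binaryChannels),
                 dimnames = list(as.character(labels), names(binaryChannels)))
  for (p in names(binaryChannels)) {
    ch <- as.matrix(binaryChannels[[p]])
    if (!identical(dim(ch), dim(segmentation)))
      stop(sprintf("channel '%s' shape does not match the segmentation", p))
    pos <- tapply(as.numeric(ch[inside]), segVec, sum)
    pos[is.na(pos)] <- 0
    vals[, p] <- as.numeric(pos) / areas
  }
  if (is.null(offsets))
    offsets <- setNames(rep(NA_real_, length(binaryChannels)),
                        names(binaryChannels))
  new("AbundanceMatrix", values = vals, window = as.integer(window),
      offsets = offsets, sigma = as.numeric(sigma))
}

#' Quantify protein abundances from raw channels
#'
#' Convenience driver: adaptively binarizes every raw channel (offset =
#' per-channel standard deviation) and tabulates fractional positivity
#' per segment.
#'
#' @param channels named list of raw intensity matrices.
#' @param segmentation integer label matrix.
#' @inheritParams adaptiveBinarize
#' @return an [AbundanceMatrix-class].
#' @export
quantifyAbundance <- function(channels, segmentation, window = 201L,
                              sigma = NULL) {
  bin <- lapply(channels, adaptiveBinarize, window = window, sigma = sigma)
  offsets <- vapply(bin, attr, numeric(1), which = "offset")
  sig <- attr(bin[[1]], "sigma")
  abundanceMatrix(bin, segmentation, window = window,
                  offsets = offsets, sigma = sig)
}

#' @rdname accessors
#' @export
setMethod("abundanceValues", "AbundanceMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("cellIds", "AbundanceMatrix", function(x, ...) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("nCells", "AbundanceMatrix", function(x, ...) nrow(x@values))

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix: %d cells x %d proteins\n",
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  proteins: %s\n",
              paste(colnames(object@values), collapse = ", ")))
  if (!is.na(object@window))
    cat(sprintf("  binarization: window %d, sigma %.2f\n",
                object@window, object@sigma))
})

#' Read a channel stack and manifest
#'
#' Reads per-protein channels from a multi-page TIFF together with a
#' channel manifest CSV (`channel_index,protein_name`), returning a
#' named list of intensity matrices.  Label masks are read with
#' `as.is = TRUE` to preserve integer labels.
#'
#' @param stackPath path to a multi-page TIFF.
#' @param manifestPath path to the manifest CSV.
#' @return named list of numeric matrices.
#' @export
readChannelStack <- function(stackPath, manifestPath) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  manifest <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("channel_index", "protein_name")
  if (!all(need %in% names(manifest)))
    stop(sprintf("channel manifest '%s': missing required column(s): %s",
                 manifestPath, paste(setdiff(need, names(manifest)),
                                     collapse = ", ")))
  pages <- tiff::readTIFF(stackPath, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- lapply(manifest$channel_index, function(i) {
    if (i < 1 || i > length(pages))
      stop("manifest channel_index ", i, " out of range (stack has ",
           length(pages), " pages)")
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    storage.mode(m) <- "double"
    m
  })
  names(out) <- manifest$protein_name
  out
}

#' Read an integer label mask TIFF
#' @param path TIFF path.
#' @return integer matrix.
#' @export
readLabelMask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF masks requires the 'tiff' package")
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}
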