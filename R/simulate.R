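#' Configuration for the synthetic tissue generator
#'
#' Defines a cohort of simulated tissue samples in three (by default)
#' conditions.  Cell centroids come from a jittered grid; cell-type
#' labels come from a nearest-center interaction process: cluster
#' centers are seeded uniformly over the domain and annotated with
#' types drawn from the target frequencies, and each cell adopts the
#' type of its nearest center with probability
#' `exp(-d / (beta * s))` (d = distance to the center, s = typical
#' center spacing), falling back to an independent draw from the target
#' frequencies.  `beta = 0` yields fully random labels; large `beta`
#' yields strongly segregated same-type patches.
#'
#' A focal cell type (the analogue of tumor T cells) receives special
#' treatment.  The mosaic carries only the non-focal types and is
#' identical in distribution across conditions, and every sample has
#' the exact target type composition, so conditions differ purely in
#' how the focal type is arranged.  In each condition a fraction
#' `focalClustered` of the focal cells is planted as compact clusters
#' at the `nFocalSites` focal sites of the template (the rest is
#' scattered at random), and within `mixingRadius` cell spacings of a
#' focal site, cells are re-labeled by an independent draw from the
#' target frequencies with probability `focalMixing`.  A case
#' condition with `focalClustered > 0` and `focalMixing > 0` therefore
#' shows the planted signature of a focal type that clusters and
#' simultaneously sits in tissue with higher cell-type mixing:
#' elevated focal egophily and elevated focal local entropy.
#'
#' @param conditions condition names; the first is the "case".
#' @param samplesPerCondition samples per condition (default 20).
#' @param cellsPerSample cells per sample (default 3000).
#' @param typeFreqs named vector of target cell-type frequencies
#'   (must sum to 1).
#' @param focalType name of the focal type.
#' @param beta baseline clustering strength, one value per condition
#'   (recycled).
#' @param focalClustered fraction of focal cells planted as compact
#'   clusters at the template's focal sites, per condition (default:
#'   0.7 for the case, 0 elsewhere).
#' @param focalMixing mixing parameter per condition in `[0, 1]`
#'   (default: 0.9 for the case, 0 elsewhere).
#' @param mixingRadius radius of the mixing ring around focal sites,
#'   in units of the cell-grid spacing (default 6, about the reach of
#'   a 5-hop neighborhood).
#' @param centersPerSample number of mosaic cluster centers.
#' @param nFocalSites number of focal cluster sites in the template.
#' @param spacing grid spacing in pixels between neighbouring cells.
#' @param jitter uniform jitter half-width as a fraction of `spacing`.
#' @param cellRadius,nucleusRadius disc radii (pixels) used when
#'   rendering channels.
#' @param exprRange per-cell marker expression fraction range for
#'   cells of the marker's own type (drawn uniformly).
#' @param backgroundRate per-pixel positive rate outside the marker's
#'   own cells.
#' @param saltPepperRate per-pixel impulse noise rate (half salt, half
#'   pepper).
#' @param fgIntensity,bgIntensity rendered foreground/background mean
#'   intensities.
#' @param orphanFraction fraction of cells rendered without a membrane
#'   label (exercises membrane completion).
#' @param seed master seed; all child streams derive from it via
#'   [childSeed()].
#' @return a list of class `TissueSimConfig`.
#' @export
tissueSimConfig <- function(conditions = c("case", "ctrl1", "ctrl2"),
                            samplesPerCondition = 20L,
                            cellsPerSample = 3000L,
                            typeFreqs = c(Tcell = 0.15, basalKC = 0.20,
                                          suprabasalKC = 0.25,
                                          fibroblast = 0.15,
                                          endothelial = 0.10,
                                          macrophage = 0.10,
                                          unknown = 0.05),
                            focalType = "Tcell",
                            beta = 8.0,
                            focalClustered = NULL,
                            focalMixing = NULL,
                            mixingRadius = 6,
                            centersPerSample = 40L,
                            nFocalSites = 3L,
                            spacing = 32,
                            jitter = 0.1,
                            cellRadius = 12,
                            nucleusRadius = 5,
                            exprRange = c(0.55, 0.95),
                            backgroundRate = 0.003,
                            saltPepperRate = 0.001,
                            fgIntensity = 200,
                            bgIntensity = 15,
                            orphanFraction = 0.2,
                            seed = 1L) {
  nc <- length(conditions)
  beta <- rep_len(beta, nc)
  if (is.null(focalClustered)) {
    focalClustered <- rep(0, nc)
    focalClustered[1] <- 0.7
  } else focalClustered <- rep_len(focalClustered, nc)
  if (is.null(focalMixing)) {
    focalMixing <- rep(0, nc)
    focalMixing[1] <- 0.9
  } else focalMixing <- rep_len(focalMixing, nc)
  cfg <- list(conditions = as.character(conditions),
              samplesPerCondition = as.integer(samplesPerCondition),
              cellsPerSample = as.integer(cellsPerSample),
              typeFreqs = typeFreqs, focalType = focalType,
              beta = setNames(beta, conditions),
              focalClustered = setNames(focalClustered, conditions),
              focalMixing = setNames(focalMixing, conditions),
              mixingRadius = mixingRadius,
              centersPerSample = as.integer(centersPerSample),
              nFocalSites = as.integer(nFocalSites),
              spacing = spacing, jitter = jitter,
              cellRadius = cellRadius, nucleusRadius = nucleusRadius,
              exprRange = exprRange, backgroundRate = backgroundRate,
              saltPepperRate = saltPepperRate,
              fgIntensity = fgIntensity, bgIntensity = bgIntensity,
              orphanFraction = orphanFraction,
              seed = as.integer(seed))
  class(cfg) <- "TissueSimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (abs(sum(cfg$typeFreqs) - 1) > 1e-8)
    stop("typeFreqs must sum to 1")
  if (any(cfg$typeFreqs < 0)) stop("typeFreqs must be non-negative")
  if (is.null(names(cfg$typeFreqs))) stop("typeFreqs must be named")
  if (!cfg$focalType %in% names(cfg$typeFreqs))
    stop("focalType must appear in typeFreqs")
  if (any(cfg$beta < 0))
    stop("beta must be non-negative")
  if (any(cfg$focalClustered < 0 | cfg$focalClustered > 1))
    stop("focalClustered must lie in [0, 1]")
  if (any(cfg$focalMixing < 0 | cfg$focalMixing > 1))
    stop("focalMixing must lie in [0, 1]")
  if (cfg$backgroundRate < 0 || cfg$backgroundRate > 1 ||
      cfg$saltPepperRate < 0 || cfg$saltPepperRate > 1)
    stop("noise rates must lie in [0, 1]")
  if (cfg$cellsPerSample < 3) stop("cellsPerSample must be at least 3")
  if (cfg$nFocalSites < 1) stop("nFocalSites must be at least 1")
  invisible(cfg)
}

#' @export
print.TissueSimConfig <- function(x, ...) {
  cat(sprintf("TissueSimConfig: %d conditions x %d samples x %d cells\n",
              length(x$conditions), x$samplesPerCondition, x$cellsPerSample))
  cat(sprintf("  focal type '%s'; beta = %s; focalClustered = %s; focalMixing = %s\n",
              x$focalType, paste(x$beta, collapse = "/"),
              paste(x$focalClustered, collapse = "/"),
              paste(x$focalMixing, collapse = "/")))
  invisible(x)
}

# cohort-level tissue architecture template: the non-focal patch mosaic
# (cluster centers with types) and the focal sites are laid out once and
# shared by every sample of the cohort, emulating sections drawn from a
# common anatomical architecture.  With a shared template, conditions
# differ only through the planting parameters, and matched-parameter
# conditions are exchangeable at the cell level.
simulateCenterTemplate <- function(cfg) {
  n <- cfg$cellsPerSample
  side <- ceiling(sqrt(n))
  L <- side * cfg$spacing
  types <- names(cfg$typeFreqs)
  # the mosaic carries only the non-focal types; the focal type enters
  # per condition through planted clusters and scattered cells
  nonFocal <- setdiff(types, cfg$focalType)
  subFreq <- cfg$typeFreqs[nonFocal] / sum(cfg$typeFreqs[nonFocal])
  K <- cfg$centersPerSample
  nPer <- pmax(1L, round(subFreq * K))
  centerType <- rep(nonFocal, nPer)
  if (length(centerType) > K) centerType <- centerType[seq_len(K)]
  centerType <- sample(centerType)
  K <- length(centerType)
  nSites <- cfg$nFocalSites
  # stratified placement: one point per grid block regularizes patch
  # sizes; focal sites go to interior blocks (so planted clusters are
  # not truncated by the border) at greedy max-min separation
  gK <- ceiling(sqrt(K + nSites))
  blocks <- seq_len(gK * gK)
  bx <- (blocks - 1) %% gK
  by <- (blocks - 1) %/% gK
  interior <- bx > 0 & bx < gK - 1 & by > 0 & by < gK - 1
  if (sum(interior) < nSites) interior <- rep(TRUE, length(blocks))
  intBlocks <- blocks[interior]
  focBlocks <- sample(intBlocks, 1)
  while (length(focBlocks) < nSites) {
    cand <- setdiff(intBlocks, focBlocks)
    dmin <- vapply(cand, function(b) {
      min(pmax(abs(bx[b] - bx[focBlocks]), abs(by[b] - by[focBlocks])))
    }, numeric(1))
    best <- cand[dmin == max(dmin)]
    focBlocks <- c(focBlocks, if (length(best) > 1) sample(best, 1) else best)
  }
  centerBlocks <- sample(setdiff(blocks, focBlocks), K)
  bw <- L / gK
  blockPoint <- function(b) {
    cbind((((b - 1) %% gK) + runif(length(b), 0.2, 0.8)) * bw,
          (((b - 1) %/% gK) + runif(length(b), 0.2, 0.8)) * bw)
  }
  cpts <- blockPoint(centerBlocks)
  spts <- blockPoint(focBlocks)
  list(cx = cpts[, 1], cy = cpts[, 2], centerType = centerType,
       siteX = spts[, 1], siteY = spts[, 2], L = L, side = side)
}

# one sample's centroids and labels; assumes RNG already seeded
simulateSampleCells <- function(cfg, cond, template) {
  n <- cfg$cellsPerSample
  side <- template$side
  gridIdx <- sample(side * side, n)
  gx <- ((gridIdx - 1) %% side)
  gy <- ((gridIdx - 1) %/% side)
  x <- (gx + 0.5) * cfg$spacing + runif(n, -cfg$jitter, cfg$jitter) * cfg$spacing
  y <- (gy + 0.5) * cfg$spacing + runif(n, -cfg$jitter, cfg$jitter) * cfg$spacing
  types <- names(cfg$typeFreqs)
  # non-focal mosaic, identical in distribution across conditions
  centerType <- template$centerType
  cx <- template$cx
  cy <- template$cy
  K <- length(centerType)
  s <- template$L / sqrt(K)
  d2 <- outer(x, cx, function(a, b) (a - b)^2) +
    outer(y, cy, function(a, b) (a - b)^2)
  nearest <- max.col(-d2, ties.method = "first")
  dNear <- sqrt(d2[cbind(seq_len(n), nearest)])
  tau <- centerType[nearest]
  beta <- cfg$beta[cond]
  pAdopt <- if (beta > 0) exp(-dNear / (beta * s)) else rep(0, n)
  adopt <- runif(n) < pAdopt
  lab <- ifelse(adopt, tau,
                sample(types, n, replace = TRUE, prob = cfg$typeFreqs))
  target <- largestRemainderCounts(cfg$typeFreqs, n)
  dSite2 <- outer(x, template$siteX, function(a, b) (a - b)^2) +
    outer(y, template$siteY, function(a, b) (a - b)^2)
  m <- cfg$focalMixing[cond]
  if (m > 0) {
    # mixing ring: within mixingRadius cell spacings of a focal site,
    # cells are re-labeled by an independent draw with probability m --
    # planting mixed tissue around the focal clusters
    dF <- sqrt(do.call(pmin, lapply(seq_len(ncol(dSite2)),
                                    function(k) dSite2[, k, drop = TRUE])))
    hit <- dF < cfg$mixingRadius * cfg$spacing & (runif(n) < m)
    if (any(hit))
      lab[hit] <- sample(types, sum(hit), replace = TRUE, prob = cfg$typeFreqs)
  }
  # planted focal clusters: a focalClustered fraction of the focal cells
  # is placed as compact clusters of fixed size at the focal sites
  planted <- integer(0)
  fc <- cfg$focalClustered[cond]
  if (fc > 0) {
    nSites <- ncol(dSite2)
    nClustered <- round(fc * target[cfg$focalType])
    perSite <- largestRemainderCounts(rep(1 / nSites, nSites), nClustered)
    for (k in seq_len(nSites)) {
      if (perSite[k] == 0) next
      nearestCells <- order(dSite2[, k])[seq_len(perSite[k])]
      lab[nearestCells] <- cfg$focalType
      planted <- c(planted, nearestCells)
    }
  }
  # repair to the exact target composition (largest-remainder counts):
  # every sample carries identical type fractions, so between-condition
  # differences are purely differences in spatial mixing, as planted;
  # planted focal clusters are never relabeled
  lab <- repairComposition(lab, types, target,
                           preferred = setdiff(which(!adopt), planted),
                           protected = planted)
  data.frame(x = x, y = y, cell_type = lab, stringsAsFactors = FALSE)
}

#' Simulate a synthetic tissue cohort
#'
#' Generates the cell table of a full cohort under a
#' [tissueSimConfig()].  Fully deterministic given the config's master
#' seed (per-sample child streams; sample order does not matter).
#'
#' @param config a `TissueSimConfig`.
#' @return a cohort cell table (see [validateCellTable()]).
#' @export
simulateTissue <- function(config) {
  validateSimConfig(config)
  template <- withSeed(childSeed(config$seed, "template"),
                       simulateCenterTemplate(config))
  parts <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    for (si in seq_len(config$samplesPerCondition)) {
      sid <- sprintf("%s_s%02d", cond, si)
      df <- withSeed(childSeed(config$seed, "tissue", ci, si),
                     simulateSampleCells(config, cond, template))
      df$cell_id <- sprintf("%s_c%04d", sid, seq_len(nrow(df)))
      df$sample_id <- sid
      df$condition <- cond
      parts[[sid]] <- df[, c("cell_id", "x", "y", "sample_id",
                             "condition", "cell_type")]
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  validateCellTable(out)
}

# integer counts summing to n, proportional to freqs (largest remainder)
largestRemainderCounts <- function(freqs, n) {
  raw <- freqs * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(freqs))
}

# relabel randomly chosen cells of surplus types to deficit types;
# cells in `preferred` (non-adopted, i.e. already randomly labeled)
# are relabeled first so that planted patches stay intact, and cells in
# `protected` are never relabeled
repairComposition <- function(lab, types, target, preferred = integer(0),
                              protected = integer(0)) {
  cnt <- table(factor(lab, levels = types))
  for (t in types) {
    deficit <- target[t] - cnt[t]
    if (deficit <= 0) next
    surplus <- names(cnt)[cnt > target[names(cnt)]]
    permute <- function(v) if (length(v) > 1) sample(v) else v
    cand <- setdiff(which(lab %in% surplus), protected)
    prefCand <- intersect(preferred, cand)
    pool <- c(permute(prefCand), permute(setdiff(cand, prefCand)))
    take <- integer(0)
    for (i in pool) {
      if (length(take) >= deficit) break
      src <- lab[i]
      if (cnt[src] > target[src]) {
        take <- c(take, i)
        cnt[src] <- cnt[src] - 1L
      }
    }
    lab[take] <- t
    cnt[t] <- cnt[t] + length(take)
  }
  lab
}

rasterDisc <- function(mask, cx, cy, r, value) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  inside <- outer((rr - cy)^2, (cc - cx)^2, "+") <= r^2
  block <- mask[rr, cc, drop = FALSE]
  block[inside] <- value
  mask[rr, cc] <- block
  mask
}

#' Render marker channels and label masks for one simulated sample
#'
#' Renders each cell as a nucleus disc inside a cell disc on a pixel
#' grid matching the cell table's coordinates, and produces one
#' intensity channel per marker protein.  Cells of a marker's own type
#' express the marker in a per-cell fraction of their pixels (drawn
#' from `config$exprRange`); all other pixels are positive at the
#' background rate.  Salt-and-pepper noise is added at the configured
#' rate.  A configured fraction of cells is left out of the cell mask
#' ("orphan" nuclei) to exercise [completeMembranes()].
#'
#' @param cells cell table of a single sample (from [simulateTissue()]).
#' @param config the `TissueSimConfig` used to generate it.
#' @return a list: `channels` (named list of intensity matrices, one
#'   per marker, named `M_<type>`), `nuclei` (nucleus label mask),
#'   `cellsMask` (cell label mask with orphans missing), `truth`
#'   (the cell table with columns `label` (mask label) and `orphan`),
#'   and `panel` (data.frame marker/protein to type).
#' @export
simulateChannels <- function(cells, config) {
  validateSimConfig(config)
  stopifnot(length(unique(cells$sample_id)) == 1)
  rc <- config$cellRadius; rn <- config$nucleusRadius
  # pixel (row, col) = (y + 1, x + 1); add a margin of one spacing
  nrPix <- ceiling(max(cells$y) + config$spacing)
  ncPix <- ceiling(max(cells$x) + config$spacing)
  n <- nrow(cells)
  types <- setdiff(names(config$typeFreqs), "unknown")
  seed <- childSeed(config$seed, "channels", cells$sample_id[1])
  withSeed(seed, {
    nuclei <- matrix(0L, nrPix, ncPix)
    cellsMask <- matrix(0L, nrPix, ncPix)
    orphan <- runif(n) < config$orphanFraction
    for (i in seq_len(n)) {
      cxPix <- cells$x[i] + 1
      cyPix <- cells$y[i] + 1
      nuclei <- rasterDisc(nuclei, cxPix, cyPix, rn, i)
      if (!orphan[i])
        cellsMask <- rasterDisc(cellsMask, cxPix, cyPix, rc, i)
    }
    fullMask <- matrix(0L, nrPix, ncPix)
    for (i in seq_len(n)) {
      fullMask <- rasterDisc(fullMask, cells$x[i] + 1, cells$y[i] + 1, rc, i)
    }
    channels <- list()
    for (t in types) {
      ch <- matrix(config$bgIntensity, nrPix, ncPix) +
        matrix(rnorm(nrPix * ncPix, 0, max(1e-3, config$bgIntensity / 5)),
               nrPix, ncPix)
      own <- which(cells$cell_type == t)
      exprFrac <- runif(n, config$exprRange[1], config$exprRange[2])
      inCell <- which(fullMask > 0L)
      cellOf <- fullMask[inCell]
      isOwn <- cells$cell_type[cellOf] == t
      pPos <- ifelse(isOwn, exprFrac[cellOf], config$backgroundRate)
      pos <- inCell[runif(length(inCell)) < pPos]
      ch[pos] <- config$fgIntensity + rnorm(length(pos), 0,
                                            config$fgIntensity / 20)
      # background positives outside any cell
      outCell <- which(fullMask == 0L)
      bgPos <- outCell[runif(length(outCell)) < config$backgroundRate]
      ch[bgPos] <- config$fgIntensity + rnorm(length(bgPos), 0,
                                              config$fgIntensity / 20)
      # impulse noise
      npix <- nrPix * ncPix
      salt <- which(runif(npix) < config$saltPepperRate / 2)
      pepper <- which(runif(npix) < config$saltPepperRate / 2)
      ch[salt] <- config$fgIntensity * 1.5
      ch[pepper] <- 0
      ch[ch < 0] <- 0
      channels[[paste0("M_", t)]] <- ch
    }
    truth <- cells
    truth$label <- seq_len(n)
    truth$orphan <- orphan
    list(channels = channels, nuclei = nuclei, cellsMask = cellsMask,
         truth = truth,
         panel = data.frame(protein = paste0("M_", types), type = types,
                            gene = paste0("G", seq_along(types)),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a reference expression table with designed marker structure
#'
#' Builds a cluster-level reference in which every cell type has one
#' exclusive high-expression marker gene: clusters of a type express
#' the type's own marker highly (around 50) and all other markers at a
#' low level (below 3), so that the spread score ranks each type's own
#' marker first by construction.  Each type gets 1-3 clusters of
#' random size.
#'
#' In addition to the measured panel, the reference carries
#' `extraTypes`: cell types whose marker genes are not among the
#' measured proteins (the reference atlas knows more types than the
#' antibody panel can see).  The assignment protocol then stops with
#' such a type remaining, labeling leftover cells "unknown".
#'
#' @param panel data.frame with columns `type` and `gene` (one marker
#'   gene per type), e.g. the `panel` element of [simulateChannels()].
#' @param seed RNG seed.
#' @param extraTypes names of additional reference-only cell types.
#' @return a [ReferenceExpression-class].
#' @export
simulateReference <- function(panel, seed = 1L,
                              extraTypes = "granulocyte") {
  stopifnot(all(c("type", "gene") %in% names(panel)))
  if (nrow(panel) < 2) stop("need at least two cell types")
  if (length(extraTypes))
    panel <- rbind(panel[, c("type", "gene")],
                   data.frame(type = extraTypes,
                              gene = paste0("Gx_", extraTypes)))
  withSeed(childSeed(seed, "reference"), {
    rows <- list()
    sizes <- numeric(0)
    typesOf <- character(0)
    for (i in seq_len(nrow(panel))) {
      nClust <- sample(1:3, 1)
      for (k in seq_len(nClust)) {
        expr <- runif(nrow(panel), 0, 3)
        expr[i] <- runif(1, 40, 60)
        rows[[length(rows) + 1]] <- expr
        sizes <- c(sizes, sample(50:500, 1))
        typesOf <- c(typesOf, panel$type[i])
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- panel$gene
    rownames(m) <- sprintf("c-%02d", seq_len(nrow(m)))
    referenceExpression(m, sizes, typesOf)
  })
}
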