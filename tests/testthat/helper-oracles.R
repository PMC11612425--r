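# Independent reference implementations used as test oracles.  These are
# deliberately naive (enumeration, per-pixel loops, per-vertex BFS) and
# share no code with the package's computational kernels.

# Delaunay edges by empty-circumcircle check over all point triples.
bruteDelaunayEdges <- function(x, y) {
  n <- length(x)
  edges <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 + 1e-12)))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  e <- unique(t(apply(edges, 1, sort)))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Delaunay edges from an independent computational-geometry library
# (scipy), invoked through the system python.
scipyDelaunayEdges <- function(x, y) {
  ptsFile <- tempfile(fileext = ".csv")
  outFile <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = x, y = y), ptsFile, row.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from scipy.spatial import Delaunay\n",
    "pts = np.loadtxt(%s, delimiter=',', skiprows=1)\n",
    "tri = Delaunay(pts)\n",
    "edges = set()\n",
    "for s in tri.simplices:\n",
    "    for a in range(3):\n",
    "        for b in range(a + 1, 3):\n",
    "            e = (min(s[a], s[b]) + 1, max(s[a], s[b]) + 1)\n",
    "            edges.add(e)\n",
    "import csv\n",
    "with open(%s, 'w') as f:\n",
    "    for e in sorted(edges):\n",
    "        f.write('%%d,%%d\\n' %% e)\n"),
    deparse(ptsFile), deparse(outFile))
  scriptFile <- tempfile(fileext = ".py")
  writeLines(script, scriptFile)
  status <- system2("python", scriptFile, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/scipy oracle failed")
  m <- as.matrix(read.csv(outFile, header = FALSE))
  dimnames(m) <- NULL
  m
}

# Per-cell local scores computed naively from khopNeighborhood().
naiveLocalScores <- function(graph, r) {
  ids <- cellIds(graph)
  lab <- cellTypes(graph)
  K <- length(typeUniverse(graph))
  ent <- hom <- ego <- setNames(numeric(length(ids)), ids)
  for (cid in ids) {
    nb <- khopNeighborhood(graph, cid, r)
    mlab <- lab[nb$members]
    p <- table(factor(mlab, levels = typeUniverse(graph))) / length(mlab)
    p <- p[p > 0]
    ent[cid] <- if (K > 1) -sum(p * log(p)) / log(K) else 0
    ie <- nb$inducedEdges
    hom[cid] <- if (nrow(ie) == 0) NA_real_ else
      mean(lab[ie[, 1]] == lab[ie[, 2]])
    ego[cid] <- mean(mlab == lab[cid])
  }
  list(entropy = ent, homophily = hom, egophily = ego)
}

# Naive adaptive binarization: per-pixel 2-D Gaussian-weighted window
# mean with symmetric reflection, mirroring the documented semantics
# (channel centered by its mean before smoothing).
naiveAdaptiveBinarize <- function(x, window, sigma, offset) {
  reflectIdx <- function(i, n) {
    while (i < 1 || i > n) i <- if (i < 1) 1 - i else 2 * n + 1 - i
    i
  }
  half <- window %/% 2
  g <- exp(-((seq_len(window) - 1 - half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  w2 <- outer(g, g)
  xc <- x - mean(x)
  out <- matrix(0L, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    s <- 0
    for (a in seq_len(window)) for (b in seq_len(window)) {
      s <- s + w2[a, b] * xc[reflectIdx(i + a - 1 - half, nrow(x)),
                             reflectIdx(j + b - 1 - half, ncol(x))]
    }
    out[i, j] <- as.integer(xc[i, j] > s + offset)
  }
  out
}

# Exact two-sided MWU p value by enumeration of all group assignments.
enumMwuP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  combos <- combn(n1 + n2, n1)
  uOf <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  us <- apply(combos, 2, uOf)
  uObs <- uOf(seq_len(n1))
  mu <- n1 * n2 / 2
  pLe <- mean(us <= uObs)
  pGe <- mean(us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# A seeded random labeled graph (Erdos-Renyi style plus a spanning path
# so it is connected).
randomLabeledGraph <- function(n, nTypes, pEdge = 0.1, seed = 1) {
  withr::local_seed(seed)
  edges <- cbind(seq_len(n - 1), 2:n)  # spanning path
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(extra)) < pEdge
  edges <- unique(rbind(edges, extra[keep, , drop = FALSE]))
  labels <- sample(LETTERS[seq_len(nTypes)], n, replace = TRUE)
  spatialCellGraph(sprintf("c%03d", seq_len(n)), edges, labels,
                   typeUniverse = LETTERS[seq_len(nTypes)])
}

# Star graph: hub of type A with nLeaves leaves of type B.
starGraph <- function(nLeaves = 3) {
  ids <- c("hub", sprintf("leaf%d", seq_len(nLeaves)))
  spatialCellGraph(ids, cbind(rep(1, nLeaves), 1 + seq_len(nLeaves)),
                   c("A", rep("B", nLeaves)), typeUniverse = c("A", "B"))
}

pathGraph <- function(labels) {
  n <- length(labels)
  spatialCellGraph(letters[seq_len(n)], cbind(seq_len(n - 1), 2:n), labels)
}
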