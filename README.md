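# spatialhet

Spatial heterogeneity scoring for cell graphs from multiplexed tissue
images.

## What it does and for whom

Multiplexed tissue imaging (MELC, MIBI, CODEX, ...) turns one tissue
section into per-protein intensity channels plus a cell segmentation.
Once every cell has a position and a type label, each sample becomes a
*spatial cell graph*: vertices are cells, edges connect spatially
adjacent cells (Delaunay neighbours of the centroids).  `spatialhet`
is for researchers who want to ask whether the *spatial organisation*
of cell types — not their mere composition — differs between patient
groups, e.g. between cutaneous T-cell lymphoma (CTCL) and its
inflammatory mimics.

With $G = (V, E, \lambda)$ the labeled graph of one sample, $T$ the
cohort-wide label set and $p_S(t)$ the fraction of type $t$ in a cell
set $S$, the package computes two sample-level scores

$$H(G) = -\frac{1}{\log |T|}\sum_{t \in T} p_V(t)\,\log p_V(t),
\qquad
h(G) = \frac{1}{|E|}\sum_{cc' \in E} [\lambda(c) = \lambda(c')],$$

and three cell-level scores on the r-hop neighbourhood
$N_r(c) = \{c' : d_G(c, c') \le r\}$ with induced edges $E_{N_r(c)}$:
local entropy $H_r(c)$ (entropy of $p_{N_r(c)}$, same normalisation),
local homophily $h_r(c)$ (monochromatic fraction of $E_{N_r(c)}$) and
egophily $e_r(c) = p_{N_r(c)}(\lambda(c))$.  Cohort inference uses
two-sided Mann–Whitney U tests with family-wise Bonferroni correction,
plus label-permutation and subsampling robustness checks.

The package also provides the supporting pre-processing — adaptive
thresholding of protein channels into fractional abundances, membrane
completion around orphan nuclei, and iterative rule-based cell typing
against an HPA-style reference — and a fully seeded synthetic-tissue
generator used to validate the whole pipeline end to end.  See the
methods vignette (`vignettes/spatial-heterogeneity-methods.Rmd`) for
models, assumptions and design choices.

## Worked example

```r
library(spatialhet)

## a seeded synthetic cohort: 3 conditions x 4 samples x 300 cells;
## the "case" condition plants clustered focal cells in mixed tissue
cfg    <- tissueSimConfig(samplesPerCondition = 4, cellsPerSample = 300,
                          centersPerSample = 12, seed = 7)
cells  <- simulateTissue(cfg)
scores <- computeAllScores(cells, radii = c(1, 5))
tests  <- testScores(scores, nRadiiFamily = 10)

subset(tests, cell_type == "Tcell" & radius == 5 & cond_a == "case" &
              score %in% c("local_entropy", "egophily"))
#>             score cond_a cond_b n_a n_b     U        p   m    p_adj
#> 43  local_entropy   case  ctrl1 180 180 26558 9.50e-26 210 1.99e-23
#> 44  local_entropy   case  ctrl2 180 180 25812 2.13e-22 210 4.47e-20
#> 127      egophily   case  ctrl1 180 180 28456 2.22e-35 210 4.66e-33
#> 128      egophily   case  ctrl2 180 180 28260 2.58e-34 210 5.42e-32
```

Each row compares the pooled per-cell scores of the focal type between
two conditions: the planted case shows significantly elevated local
entropy *and* egophily at radius 5 (adjusted for the local family of 3
condition pairs x 7 cell types x 10 radii, m = 210) — focal cells
cluster together while sitting in tissue with higher cell-type mixing,
the organisational signature the scores are designed to detect.

Single scores are available directly; for the star graph with one
type-A hub and three type-B leaves:

```r
star <- spatialCellGraph(c("hub", "l1", "l2", "l3"),
                         cbind(rep(1, 3), 2:4), c("A", "B", "B", "B"))
localEntropy(star, 1)[["hub"]]  #> 0.8112781
egophily(star, 1)[["hub"]]      #> 0.25
```

A thin command-line wrapper with subcommands `simulate`, `graph`,
`score`, `quantify`, `typing`, `stats` and `pipeline` is installed at
`inst/scripts/spatialhet`.

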