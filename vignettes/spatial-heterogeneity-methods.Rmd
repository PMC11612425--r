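---
title: "Quantifying spatial tissue heterogeneity on cell graphs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial tissue heterogeneity on cell graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialhet)
```

# The problem

Multiplexed tissue imaging (cyclic immunofluorescence platforms such as
MELC, MIBI or CODEX) yields, for one tissue section, a stack of aligned
per-protein intensity images plus a cell segmentation.  After cell-type
assignment, each sample becomes a *spatial cell graph*: vertices are
cells annotated with a type, and edges connect spatially adjacent
cells.  `spatialhet` quantifies how strongly cell types mix in such
graphs — globally per sample and locally around each cell — and tests
whether that spatial organisation differs between patient groups (for
instance a cutaneous T-cell lymphoma cohort against the inflammatory
mimics atopic dermatitis and psoriasis).

# The spatial graph

`buildDelaunayGraph()` connects two cells iff they are neighbours in
the Delaunay triangulation of the centroid point set.  The
triangulation needs no tuning parameters — unlike k-nearest-neighbour
or distance-threshold graphs, whose k or threshold is hard to choose in
a principled way — and it is connected for every finite point set.
Design choices:

* **No edge pruning.**  The graph is exactly the triangulation; long
  boundary edges are kept.  Scores are computed on hop distance, so a
  single long hull edge carries the same weight as a short interior
  edge.
* **Degenerate inputs.**  Duplicate centroids are an error (they
  indicate an upstream segmentation failure), as are fewer than three
  cells or an all-collinear point set.  Cocircular quadruples admit two
  valid diagonals; the implementation returns one deterministically,
  and all scores are invariant to the choice except through the
  (equally valid) induced edge sets.
* **Coordinates.**  x is the image column, y the row, 0-based at pixel
  centers, matching the array indexing of the imaging functions.

The triangulation kernel is an incremental Bowyer–Watson construction
with a ghost vertex for the hull, written in C++.  Orientation and
in-circle predicates evaluate in double precision with an error bound
and fall back to extended precision near degeneracy.  The test suite
checks the kernel against a brute-force empty-circumcircle oracle and
against an independent computational-geometry library.

# Heterogeneity scores

Let $G = (V, E, \lambda)$ be the graph of one sample, $T$ the *cohort-wide*
set of cell-type labels, and $p_S(t)$ the fraction of cells of type $t$
in a cell set $S$.  With $N_r(c)$ the set of cells within hop distance
$r$ of $c$ (including $c$) and $E_{N_r(c)}$ the edges with both ends in
$N_r(c)$:

* **Global entropy** $H(G) = -\log(|T|)^{-1}\sum_{t} p_V(t)\log p_V(t)$;
* **Global homophily** $h(G)$: fraction of edges joining two cells of
  equal type;
* **Local entropy** $H_r(c)$: the entropy of $p_{N_r(c)}$, normalized
  by the same $\log |T|$;
* **Local homophily** $h_r(c)$: monochromatic fraction of
  $E_{N_r(c)}$;
* **Egophily** $e_r(c) = p_{N_r(c)}(\lambda(c))$, the fraction of the
  neighborhood sharing $c$'s own type ($> 0$ by self-inclusion).

Numerical conventions: $0\log 0 = 0$; both entropies are defined as 0
when $|T| = 1$ (no heterogeneity is representable); the logarithm base
cancels in the normalization (natural log is used).  The type universe
defaults to all labels observed across the cohort, *fixed before
scoring* — per-sample universes would make entropies incomparable
between samples — and is recorded in the score-table attributes.
Cells labeled `unknown` are ordinary labeled vertices and enter all
denominators; `computeAllScores(includeUnknown = FALSE)` exposes a
filter for sensitivity analyses.  Local homophily is *missing* (not 0)
when $E_{N_r(c)}$ is empty, which cannot arise in Delaunay graphs but
can in externally supplied ones; missing values are dropped pairwise in
the downstream tests, with counts reported.

The engine computes all radii in one truncated breadth-first sweep per
cell, bucketing members and induced edges by hop level, so runtime
grows essentially linearly in the number of cells and is nearly flat in
$r$.  The default radius set is $r \in \{1,2,3,4,5,10,20,50,100,500\}$.

# Image quantification

`adaptiveBinarize()` implements locally adaptive thresholding: a pixel
is positive iff its intensity strictly exceeds the Gaussian-weighted
mean of its window (default $201 \times 201$ pixels) plus an offset
that defaults to the standard deviation of the whole channel.  The
per-channel offset absorbs global intensity differences between
protein channels; the local mean absorbs within-channel illumination
gradients; the strict inequality makes a constant channel binarize to
all zeros.  Two details are deliberate choices where convention is not
fixed: the Gaussian bandwidth is `0.3 * ((window - 1)/2 - 1) + 0.8`
pixels (the common "bandwidth proportional to window size" convention;
configurable via `sigma`), and borders reflect symmetrically.
Intensities are centered by the channel mean before smoothing — the
comparison is shift-invariant, so this is mathematically neutral, but
it makes the constant-image case exact in floating point.

`completeMembranes()` handles nuclei whose membrane the upstream
segmentation missed: the mean ratio $\rho$ of cell to nucleus
*equivalent-area radius* ($\sqrt{\text{area}/\pi}$ — "radius" is
otherwise undefined for irregular segments) is estimated from the
matched nucleus/cell pairs, and each orphan nucleus receives a disc of
radius $\rho \, r_{\text{nucleus}}$ around its centroid.  Pixels
already claimed by detected cells are never overwritten; pixels
contested by two new discs go to the nearer *centroid* (the paper-style
"closest nucleus" is ambiguous between centroid and boundary; centroid
is deterministic and cheap), and exact ties go to the lower label.

`abundanceMatrix()` then sets $A(c, p)$ to the fraction of positive
binarized pixels of protein $p$ inside segment $c$.

# Rule-based cell typing

Cell types are assigned by an iterative marker-gating protocol against
a reference expression table (for real data: the Human Protein Atlas
skin single-cell reference, read by `readHPAReference()`):

1. Cluster-level reference values are aggregated to type level by the
   size-weighted mean (`aggregateReference()`).
2. Each iteration ranks all (remaining type, gene) pairs by the spread
   score $s(t,g) = X(t,g) - \max_{t' \neq t} X(t',g)$, recomputed as
   the remaining-type set shrinks.
3. A two-component unequal-variance Gaussian mixture is fitted to each
   gene's abundances over the not-yet-assigned cells.  A gene is *good*
   iff $\mu_0 + 1.96\sigma_0 < \mu_1 - 1.96\sigma_1$ (the multiplier is
   configurable).  The first ranked pair with a good gene wins, and all
   cells with $A(c, g^\star) > \mu_1 - 1.96\sigma_1$ receive the type.
4. The protocol stops when cells or types run out, when fewer than two
   types remain (the spread is then undefined — with the skin
   reference this is the granulocyte endpoint), or when no gene is
   good; leftover cells are labeled `unknown`.

Mixture fitting uses mclust's model-based EM.  The hierarchical
initialization is deterministic, but EM can settle on a local optimum
that splits a wide positive mode instead of separating positives from
negatives, so `fitBimodal()` additionally runs ten seeded
k-means-initialized EM restarts and keeps the best log-likelihood; the
"good" decision is thereby reproducible under a fixed seed.  Fits with
a collapsed component ($\sigma < 10^{-6}$) are never good.  Ties in
the candidate ranking break by type then gene name; cells are sorted
by id before fitting, so input order does not affect the result.

# Cohort statistics

All between-condition comparisons use the two-sided Mann–Whitney U
test: exact for small untied samples ($n_1 n_2 \le 400$), otherwise
the tie-corrected normal approximation with continuity correction
(`mwuTest()` documents the exact switching rule; both variants are
exercised in the tests).  Global scores compare per-sample values;
local scores compare the cells *pooled across samples* within each
condition, per (score, cell type, radius) stratum — matching the
cohort-level analyses the package targets.  Pooling ignores patient
nesting, so a per-sample-median variant is available behind
`bySampleMedian = TRUE`; the default reproduces the pooled analysis.
Bonferroni correction is applied per score type: global families use
$m$ = number of condition pairs, local families
$m = \text{pairs} \times \text{cell types} \times \text{radii}$
(`bonferroniCutoff()`).

Two robustness checks accompany the tests, both reporting *unadjusted*
p values alongside the original ones: `permutationTest()` shuffles
condition labels across samples (preserving group sizes; one shuffle
per iteration shared by all strata) and `subsamplingTest()` redraws k
samples per condition without replacement (default k = 15, 100
iterations each).

# The synthetic-tissue generator

`simulateTissue()` generates seeded cohorts in which every module of
the package can be validated end to end.  Its default scale mirrors a
realistic skin-imaging cohort: three conditions (one case, two
controls), 20 samples per condition, 3000 cells per sample, seven cell
types including a 15% focal type (the T-cell analogue) and a 5%
`unknown` fraction.

The design separates three ingredients:

* **A cohort-wide architecture template.**  The mosaic cluster
  centers (positions and types, non-focal types only) and the focal
  cluster sites are laid out once per cohort — stratified over grid
  blocks, with the focal sites in interior blocks at maximal pairwise
  separation — and shared by every sample, emulating sections cut
  from a common anatomical architecture.  Sharing the template is
  what makes matched-parameter conditions exchangeable at the cell
  level, so that pooled Mann–Whitney p values are approximately
  uniform under the null; per-sample random architectures would add a
  sample-level random effect that the pooled test (which ignores
  nesting) mistakes for signal.
* **A non-focal mosaic.**  Each cell adopts its nearest center's type
  with probability $\exp(-d/(\beta s))$ ($s$ = typical center
  spacing), falling back to an independent draw from the target
  frequencies; $\beta = 0$ gives fully random labels, large $\beta$
  segregated patches.  The mosaic carries only non-focal types and is
  therefore identically distributed in *all* conditions; the focal
  type appears only through planting and scattering.
* **Focal planting.**  Per condition, a fraction `focalClustered` of
  the focal cells is placed as compact fixed-size clusters at the
  focal sites (default 0.7 for the case, 0 for controls — scattered
  T cells in controls, tumor-like aggregates in the case), and within
  `mixingRadius` cell spacings of a focal site (default 6, about the
  reach of a 5-hop neighborhood) labels are re-randomized with
  probability `focalMixing` (default 0.9 case / 0 controls).  This
  plants the case signature of a focal type that clusters *and* sits
  in locally mixed tissue: elevated focal egophily and elevated focal
  local entropy.  Planted clusters have fixed size, so the effect
  magnitude does not fluctuate with template geometry.

Every sample is repaired to the *exact* target composition
(largest-remainder counts; randomly-labeled cells are relabeled first
and planted clusters never): the conditions differ purely in spatial
arrangement, mirroring cohorts whose cell-type composition is not
itself discriminative.  All randomness derives from one master seed
through a documented splitting rule (`childSeed()`), so cohorts are
byte-identical across runs and independent of generation order.

`simulateChannels()` renders each cell as a nucleus disc (radius 5 px)
inside a cell disc (radius 12 px, grid spacing 32 px), withholds a
configurable fraction of membranes to exercise `completeMembranes()`,
and draws one marker channel per type: cells of the marker's type
express it in a per-cell *fraction* of their pixels, drawn uniformly
from `exprRange` (default 0.55–0.95 — per-cell expression
heterogeneity that maps directly onto the fractional-abundance
readout), over a background positive rate of 0.3% and salt-and-pepper
noise at 0.1% of pixels.  The uniform per-cell fraction is a
deliberate choice: its support lies within $1.96\sigma$ of its mean
(a uniform's half-width is $1.73\sigma$), so the mixture-based
assignment threshold $\mu_1 - 1.96\sigma_1$ excludes almost none of
the true positives, and typing recovery is limited only by pixel-level
binomial noise; segments of about 450 pixels keep that noise small.
With a Gaussian per-cell fraction, 2.5% of true positives would fall
below the threshold by construction — a ceiling that no implementation
could beat.  `simulateReference()` builds a cluster-level reference
with one exclusive high marker per type (1–3 clusters per type, so
size-weighted aggregation is exercised) plus a reference-only extra
type whose marker is unmeasured, reproducing the real-data situation
where the protocol stops with types it cannot gate.

# What the synthetic benchmarks do and do not show

The generator validates the *machinery*: score correctness, test
calibration, detection of planted mixing differences, and recovery of
planted identities through the full imaging path.  It does not emulate
real tissue morphology (no anisotropic structures such as epidermal
layers), real MELC intensity distributions, segmentation errors beyond
missing membranes, or patient-level nesting of samples — so passing
benchmarks demonstrates that the pipeline measures what it claims to
measure, not that any particular biological cohort will separate.

# Problem sizes used by the tests and the acceptance script

Validation experiments are scaled for desk runtimes, as the package's
own choice of benchmark size: detection/calibration cohorts use 3
conditions × 6 samples × 300 cells (100 seeds each; the local family
there is 3 pairs × 7 types × 10 radii, cutoff $0.05/210$); robustness
cohorts 18 samples per condition × 300 cells (k = 15, 100 iterations);
typing recovery one 900-cell sample rendered to images; the scaling
check times `computeAllScores()` at $r = 5$ on 1k–50k-cell samples and
requires a log–log slope below 1.3.  Null calibration is reported as
the fraction of per-stratum Bonferroni-corrected null tests rejecting
at $\alpha = 0.05$, the quantity the correction controls.

# Known limitations

* The pooled local tests inherit the pseudo-replication of pooling
  cells across samples; with strong sample-level heterogeneity their p
  values are anticonservative.  The permutation test (which shuffles at
  sample level) is the robust companion, and the per-sample-median
  variant offers a conservative alternative.
* Membrane completion assumes roughly isotropic cells; the
  equivalent-area radius under-serves elongated cells.
* The typing protocol is hard, rule-based gating: no doublet handling,
  no soft assignments, and its outcome depends on the reference's
  marker structure through the spread ranking.
* The Delaunay graph connects cells across tissue gaps (the
  triangulation has no notion of background); downstream scores treat
  such edges like any other adjacency.
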