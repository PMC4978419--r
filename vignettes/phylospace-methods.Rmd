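---
title: "Spectral phylogenetic space: models, choices, and limitations"
author: "phylospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phylogenetic space: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylospace)
```

## The spectral fingerprint of a tree

`phylospace` compares phylogenetic trees without assuming any generating
model.  The object at its core is the *modified graph Laplacian* (MGL) of a
rooted, ultrametric phylogeny: with $A$ the matrix of path-length distances
between **all** nodes of the tree (tips, internal nodes, and the root) and
$D$ the diagonal matrix with $D_{ii} = \sum_j A_{ij}$, the MGL is

$$ M \;=\; D - A. $$

$M$ is symmetric, has zero row sums, and is positive semidefinite, so its
spectrum is nonnegative with exactly one structural zero.  Because $A$ is
linear in the branch lengths, the whole spectrum scales linearly when the
tree is rescaled in time — a property the package tests exactly.

The *spectral density profile* is the Gaussian kernel density of the
ln-transformed nonzero eigenvalues, normalized to unit integral.  Three
statistics summarize it:

* $\lambda^*$ — the natural log of the principal eigenvalue.  It tracks the
  total evolutionary path length of the tree ("phylogenetic expansion") and
  moves one-for-one with $\ln c$ under a branch-length rescaling by $c$.
* $\psi$ — the skewness of the nonzero eigenvalue distribution.  Low
  values indicate trees whose branching is concentrated early ("stemmy");
  high values indicate recent, tip-ward branching ("tippy").  Whether this
  skewness should be taken on the raw or the ln-transformed eigenvalues is
  a genuine ambiguity; the package uses the raw spectrum because, on
  size-matched birth–death corpora, only that choice reproduces the
  statistic's documented meaning (decreasing-rate trees score lowest,
  increasing-rate trees highest; the ln variant places constant-rate trees
  below early-burst ones).  Like every moment skewness, $\psi$ is invariant
  to rescaling the tree in time.
* $\eta$ — the peak height of the unit-integral density.  Homogeneous
  branch lengths concentrate eigenvalue mass and raise the peak ("regular"
  trees); rate shifts and localized radiations flatten it.

A fourth quantity, the *eigengap modality*, is the position of the largest
gap in the descending-ranked spectrum — a count of the tree's "modes of
division".

### Numerical choices

* **Bandwidth.** Silverman's rule-of-thumb on the ln-eigenvalues, evaluated
  on a 512-point uniform grid extending three bandwidths beyond the extreme
  ln-eigenvalues.  No bandwidth is canonical for this statistic; profiles
  are comparable only within one bandwidth rule, so the rule is fixed
  package-wide and recorded in the profile object.
* **The structural zero.** A connected graph Laplacian always has one zero
  eigenvalue.  It carries no shape information and $\ln 0$ is undefined, so
  eigenvalues with $|\lambda| \le 10^{-8}\lambda_{\max}$ are excluded from
  the ln-transform.  The same exclusion is applied before the eigengap scan:
  otherwise the terminal drop from the smallest positive eigenvalue to zero
  would dominate the gaps and the modality would degenerate to the spectrum
  length.  An optional `drop_below` threshold reproduces the stricter
  convention of excluding all eigenvalues below 1 before the ln-transform.
* **$\eta$ normalization.**  $\eta$ is read off the *unit-integral*
  density, which makes it comparable across trees with different node
  counts.
* **Solver.**  Dense symmetric eigendecomposition; the package is designed
  for family-level trees (tens to hundreds of tips, matrices up to
  $\sim 1400^2$), which is well within desk scale.
* **Skewness.**  The moment (type-1) estimator $m_3/m_2^{3/2}$; spectra
  with fewer than three eigenvalues report $\psi = 0$.

## Diversification types: clustering profiles

Distances between trees are Jensen–Shannon divergences between their
profiles, computed on one shared uniform grid spanning the union of
supports, with natural logarithms (so distances live in $[0, \ln 2]$).
Two clustering routes are provided:

* **Hierarchical** (average linkage by default) with bootstrap support:
  the columns of the shared density grid are resampled with replacement,
  distances and the dendrogram recomputed, and each observed clade's
  support is the fraction of resamples reproducing it.  Clades at support
  $\ge 0.95$ are flagged significant.  What exactly is resampled in this
  kind of profile bootstrap is a genuine design choice; resampling density
  ordinates (grid columns) keeps the tree set fixed and perturbs only the
  shape information, which is the quantity the dendrogram is built from.
* **k-medoids** (PAM) across a range of candidate $k$ (default 2–10), with
  the number of clusters selected by optimum average silhouette width and
  averages above 0.5 treated as supported structure.

A per-class composition test asks whether a taxonomic class is over- or
under-represented in a cluster: class members are repeatedly thrown into
clusters with probabilities proportional to cluster sizes, and the observed
count is flagged when it falls in the lower or upper 5% tail of that null.

Robustness to input uncertainty (e.g. posterior samples of the source
trees) is quantified by rerunning the k-medoids selection per corpus and
reporting how often the same $k$ and the same assignment (up to cluster
relabeling, by maximum-agreement matching) recur.

## Phylogenetic space and its archetypes

Each tree becomes a point $(\lambda^*, \psi, \eta)$.  Because the three
statistics have incommensurate scales, all geometry is done on min–max
normalized coordinates; reported *contributions* of the statistics at an
archetype (percentages summing to 100) are the normalized vertex
coordinates divided by their sum.

The bounding geometry is found in two stages:

1. **Archetypal decomposition.**  For each candidate vertex count $k$, an
   alternating-optimization archetypal analysis is fitted: archetypes are
   convex combinations of data points (equivalently, of the data's convex
   hull vertices, which is how the implementation parameterizes them) and
   each point is approximated by a convex combination of archetypes.
   Explained variance is $1 - \mathrm{SSE}/\mathrm{SS}_{\mathrm{tot}}$.
   Fits are warm-started from the previous $k$, making explained variance
   non-decreasing in $k$; the selected $k$ is the last one whose marginal
   gain is at least 5% (configurable).
2. **Minimal enclosing refinement.**  The selected vertex set is replaced
   by a minimal-volume enclosing polytope.  For triangles this is a
   support-line search (one side of the optimal triangle is flush with a
   convex-hull edge, so the search enumerates hull-edge angles and
   optimizes the two remaining support angles numerically); for a
   full-dimensional simplex it is a closed-form inflation about the
   centroid followed by per-vertex pull-in in barycentric coordinates; for
   more vertices than $d + 1$ the centroid inflation alone is used.  The
   contract is "vertices enclose approximately all points with minimal
   volume", not a specific published algorithm.

Significance of a $k$-vertex geometry is a *t-ratio test*: the ratio of the
data's convex-hull volume to the fitted polytope volume, compared with the
same statistic on datasets whose coordinate axes are independently
shuffled.  The permutation destroys the joint geometry while preserving
margins; $p$ is the fraction of shuffled datasets with a t-ratio at least
as large as observed.  When the polytope has fewer vertices than $d + 1$
(the paper-level case of a triangle in 3-D), points are first projected
onto their leading principal plane.  The shuffling scheme and volume
estimator are package choices, documented rather than asserted to
replicate any published implementation's internals.

Trade-offs between the statistics are summarized by pairwise regressions:
candidate forms (linear, logarithmic where the predictor is positive,
quadratic, cubic) compete by AIC against an intercept-only null.  A
selected form is called significant only if it beats the null on AIC *and*
its F-test clears $\alpha$ after Bonferroni correction for the number of
candidate forms tried — the correction acknowledges that form selection on
noise would otherwise inflate the nominal error rate several-fold.

Bounding-box statistics compare two occupied regions: occupancy is the
axis-aligned bounding-box volume of one set as a percentage of the other's;
overlap is intersection over union of the two boxes.  Diversification-type
regions are full 3-D convex hulls (not 2-D projections — the package avoids
an arbitrary projection choice); membership is a half-space test, with ties
resolved by nearest hull centroid.  Rarefaction refits the polytope at
fixed $k = 3$ on bootstrap subsamples of increasing size and fits a
logarithmic saturation curve to the per-axis maximum vertex coordinates.

## The space available to trees

To chart where ultrametric, bifurcating, rooted trees *can* live at a given
$\lambda^*$, the package generates "phylogeny-type networks": a random
symmetric positive-semidefinite M-matrix with zero row sums (off-diagonals
i.i.d. $-\mathrm{Exponential}(1)$ on a dense complete graph by default —
the minimal-assumption choice, configurable), rescaled so
$\ln \lambda_{\max}$ hits a target drawn from the empirical $\lambda^*$
pool.  Dijkstra shortest paths over the implied weighted graph (weights =
off-diagonal magnitudes; the only reading that yields finite path lengths)
give a distance matrix; complete-linkage clustering turns it into a rooted
dendrogram; mean-path-length ultrametricization and random polytomy
resolution produce the final binary ultrametric tree.  Because linkage and
ultrametricization change the spectrum, the $\lambda^*$ constraint is
enforced *on the final tree* by linear branch rescaling (eigenvalues are
linear in branch lengths, so the target is hit exactly); enforcing it only
on the initial matrix is available via `constrain_after = FALSE`.

Mean-path-length ultrametricization itself follows the simplest published
variant: each internal node's age is the mean of its path lengths to its
descendant tips, with child ages clamped to parent ages when the raw means
would invert them (rare on near-clocklike input; clamped edges get length
zero).

Node counts default to 20–100 at desk scale (each graph node becomes a tip
of the reconstructed tree); the empirical corpus the package emulates spans
20–700 tips, and the range is configurable.

## Birth–death simulator and the synthetic corpus

The simulator is crown-conditioned: two lineages at $t = 0$ (time runs from
the crown toward the present), a run of exactly `age` time units, and
rejection when either crown lineage leaves no extant descendant.  This
makes the crown age exact by construction, matching how trees are binned by
crown age downstream.  Speciation rates may be constant ($b$), exponential
in time ($\alpha e^{\pm\beta t}$ — with the *decreasing* form meaning high
early rates and stemmy trees), or two-epoch (`shift`); extinction is
constant.  Events are generated by thinning against the envelope maximum of
the rate, which is exact for these bounded forms.  Extinct lineages are
pruned as the Newick string is assembled.  Trees whose surviving tip count
falls outside the richness bounds (default 20–700, the inclusion range of
the family-level corpus) are rejected and reported, never silently
retried.  Pure-birth moments ($E[N] = 2e^{bT}$ for the crown process) are
verified against simulation in the test suite.

Where published parameter ranges for this kind of simulation experiment are
typographically ambiguous, the package adopts $\alpha \in [0.01, 1]$,
$\beta \in [0.05, 0.2]$, $b \in [0.1, 0.25]$, $d \in [0, 0.1]$ as defaults
and exposes everything as configuration.

### The planted five-regime corpus

`planted_type_corpus()` is the package's stand-in for a literature-compiled
empirical corpus: five generative regimes — a small young constant-rate
category, a larger older constant-rate category, a strong early burst
(decreasing), a strong late acceleration (increasing), and a two-epoch
rate shift — with crown ages spread over roughly 10–110 My and tip counts
within 20–700.  Each regime additionally conditions on its own richness
window (a size category, like comparing small and large families), chosen
so that the between-regime separation of spectral profiles comfortably
exceeds the within-regime spread; this is what makes the corpus usable as
ground truth for planted-recovery tests of the whole pipeline.  The regime
parameters are fixed defaults, documented here, and are not meant to be
tuned per analysis.

What the generator emulates: the size and age structure of a family-level
vertebrate corpus, distinct diversification modes, exact ultrametricity.
What it does not emulate: taxon undersampling (empirical families are
included at $\ge 80$% sampling, which perturbs profiles), non-binary
source trees, calibration error in divergence times, and any correlation
structure between families (shared history above the family level).
Passing planted-recovery tests therefore demonstrates that the pipeline
separates genuinely distinct diversification modes at realistic sizes — not
that five clusters would be recovered from any empirical corpus.

## Trajectories over crown age

Trees are binned by crown age with exact Fisher–Jenks natural breaks
(dynamic programming over the sorted ages; verified against brute-force
partition enumeration).  When no bin count is given, the smallest $k$
whose goodness-of-variance fit reaches 0.9 is used, capped at 7 — the cap
matching the bin count used for class-specific trajectories.  Each bin
contributes the arithmetic mean of $(\lambda^*, \psi, \eta)$; the bin's
diversification type is the hull containing that mean (nearest centroid if
none), and its *median tree* is the tree closest to the bin mean in
min–max normalized coordinates (raw scales being incommensurate), with
ties broken by label order.  Per-statistic age trends are selected by AIC
among polynomials up to cubic with the same null-competition and
Bonferroni convention as the trade-off regressions.  Class-specific
trajectories reuse the identical code path on a subset of rows.

## Reproducibility machinery

Every stochastic operation takes an explicit integer seed; corpus
generators derive per-item seeds deterministically from the master seed, so
any single tree can be regenerated in isolation.  `run_pipeline()` fans a
single seed out to fixed per-stage seeds, serializes all tabular outputs
with stable numeric formatting (so identical configurations are
byte-identical), and writes a manifest with versions, seeds, and timings.
The test suite runs the full synthetic study twice and compares outputs
byte for byte.

### Problem sizes

The shipped defaults are desk-scale: a 150-tree synthetic study (5 regimes
x 30 trees, up to ~420 tips per tree), 512-point density grids, 60–200
bootstrap resamples and permutations in the pipeline configuration, and
20–100-node phylogeny-type networks.  All of these are parameters, and the
empirical-scale settings (10,000 networks, 1,000 bootstrap resamples,
20–700-node ranges) are reachable by configuration on a workstation.

## Known limitations

* The MGL spectrum requires a dense eigendecomposition; trees far beyond
  ~700 tips need more careful solvers than this package provides.
* Bootstrap support resamples density ordinates, not source data; it
  quantifies profile-shape stability, not phylogenetic uncertainty (use
  `cluster_stability()` with posterior-resampled corpora for the latter).
* The archetype optimizer is a local alternating scheme with deterministic
  restarts; the enclosing refinement is globally searched only for
  triangles.
* Eigengap modality is reported but intentionally not used to define the
  space; its value depends on the zero-exclusion convention documented
  above.
* A stem (root) edge present in an input Newick is ignored: it has no
  second endpoint among the tree's nodes, so it cannot contribute to any
  node-to-node path and does not enter the MGL; crown ages are likewise
  measured from the first split.
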