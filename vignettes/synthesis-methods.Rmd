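---
title: "Synthesizing low-distortion cytometry embeddings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing low-distortion cytometry embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanjay)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limitations of the package — the information a maintainer
or a skeptical user needs before trusting a plot.

## The pipeline and its assumptions

The package turns an events × channels matrix of fluorescence intensities
into a 2D or 3D scatter while controlling the worst-case change of any
pairwise distance. The stages and their assumptions:

**Network construction.** Cells become nodes; an edge joins two cells when
their Manhattan distance is at most a threshold $T$ (closed inequality, so a
pair at exactly $T$ is connected). Manhattan distance is used because
per-channel intensity differences are the natural units of cytometry
dissimilarity and no channel covariance model is assumed. Intensities are
taken raw: no compensation or logicle/asinh transform is applied, because no
preprocessing convention can be assumed on the caller's behalf —
`read_events(transform = )` is the hook for callers who want one.

**Threshold selection.** As $T$ sweeps from 0 to the data diameter, the
network moves from $N$ isolated cells to one clique; the "most informative"
network lies between. `select_threshold()` maximizes the Shannon entropy of
a topological-property distribution over a candidate grid. Which property is
a genuinely open design point; the package exposes two:

- *component-size distribution* (default): entropy peaks while the network
  is still assembling inside populations, well below the inter-population
  gap;
- *degree distribution*: on multi-population data its entropy peaks at
  thresholds that partially bridge populations, because bridging diversifies
  degrees. Measured on 1000-cell 3-population clouds, the degree criterion
  selected $T^*\approx 3700$ against an inter-population gap of $\approx
  2050$ and merged two populations (adjusted Rand 0.58), while the
  component-size criterion selected $T^*\approx 570$ and recovered the
  populations (adjusted Rand 0.998). That measurement is why component sizes
  are the default.

Ties break toward the smallest candidate. The automatic candidate grid is
the sorted distinct pairwise distances when there are at most 64 of them,
otherwise 64 quantiles of the pairwise-distance distribution — enough to
cover the isolates-to-clique sweep at bounded cost.

**Community detection.** Walktrap (igraph's implementation): short random
walks get trapped in densely connected regions, and agglomerative merging is
cut at the modularity-maximizing level. Walk length defaults to 4, the
algorithm's customary setting. Isolated nodes never enter the walk machinery
and become singleton communities — deliberate, since an outlier cell is not
evidence about any population. A consequence worth knowing: at the
entropy-optimal threshold a 1000-cell sample typically leaves a cell or two
isolated, so the partition size $n$ is "number of populations plus a few
singletons", not exactly the population count.

**Structural representation.** Each community $C_i$ is summarized by its
centroid $O_i$ and by $k$ component centroids $E_i^1..E_i^k$ from k-means
($k = 3$ when embedding into 2D, $k = 4$ for 3D — one more anchor than the
target dimension, the number trilateration needs). The structural set
$Q_1..Q_d$, $d = (k{+}1)\,n$, stands in for all cells during synthesis.
k-means uses a seeded k-means++ initialization and at most 300 iterations;
component centroids are sorted lexicographically so the structural indexing
is reproducible. Communities with fewer than $k$ points are padded with
copies of their centroid (with a warning) rather than rejected: the $d =
4n/5n$ bookkeeping that synthesis and placement rely on stays intact, and a
duplicated anchor merely degenerates gracefully to co-located grid points.

**Synthesis.** Targets are the pairwise distances of $Q_1..Q_d$ (Manhattan
by default), quantized onto a $b$-bit grid by $scale = (2^b - 1)/\max D$ and
rounding. Coordinates are unsigned $b$-bit integers; the synthesis fixes $l$
high-order bits per coordinate per refinement level. A point whose prefix
has $s$ bits can lie anywhere in a $2^{b-s} \times 2^{b-s}$ sub-square, so
for every pair the reachable squared Euclidean distance is an interval,
computed exactly by per-axis interval arithmetic
(`subsquare_distance_bounds()`). A refinement level is feasible when every
pair's interval still meets the tolerance band; after $b/l$ levels the
intervals are points and the band holds exactly — the package re-asserts
this on every returned embedding.

**Placement.** Every cell is positioned by least-squares trilateration
against its community's embedded component centroids, using the cell's
high-dimensional distances to those anchors scaled into grid units.
Least-squares (differences of squared-distance equations, QR solve) rather
than an exact solve, because synthesized anchor distances carry band
distortion and an exact intersection generally does not exist. When a
community's embedded anchors are affinely dependent the community centroid
joins as an extra anchor; if the system is still degenerate the cells are
placed at the centroid's position, with a warning.

## The tolerance band: two semantics

The distance-preservation constraint appears in two forms that are *not*
equivalent, and the package implements both:

- `band = "multiplicative"`: $(1-\varepsilon) D_{ij}^2 \le \lVert R_i - R_j
  \rVert^2 \le (1+\varepsilon) D_{ij}^2$ — the squared-distance reading of
  the per-level selection constraint. Relative error control: tight on large
  distances, brutal on small ones.
- `band = "additive"`: $\bigl| \lVert R_i - R_j \rVert - D_{ij} \bigr| \le
  \varepsilon \cdot \max D$ — the distance-preservation formulation the
  existential specification of the problem uses, and the semantics of the
  reported distortion statistic $|d(x',y') - d(x,y)|$.

`synthesize_embedding()` and `find_min_epsilon()` default to multiplicative;
the full pipeline (`sanjay_embed()`) and the method comparison
(`compare_methods()`) use additive. The reason is measured, not aesthetic:
under the multiplicative band the binding constraints are the smallest
distances, so at the feasibility limit the large-distance pairs retain slack
that the solver may spend badly — on 10-point benchmark instances the
realized maximum additive distortion came out roughly 1.7× *worse* than
classical MDS. Under the additive band the bisected $\varepsilon^*$ *is* the
worst-pair additive distortion (up to bisection tolerance), and the same
instances come out 1.2–1.7× *better* than MDS on every seed — the behavior
the benchmark tables describe. When comparing methods by additive
distortion, synthesize with the additive band.

`find_min_epsilon()` bisects $\varepsilon$ on $(0, 1]$: doubling from
`eps_init` (0.025) until a synthesis succeeds, then bisecting to `tol`
(default 0.01). Feasibility is monotone in $\varepsilon$ by construction.
Budget-exhausted searches count as failures, which can only make the
returned $\varepsilon$ conservative (never falsely small).

## The decision procedure

Each refinement level is a finite decision problem: choose one $l$-bit block
per point per axis so that all $\binom{d}{2}$ interval-band constraints
hold. The package solves it with a complete backtracking search written in
C++: points are assigned in order; each candidate block combination is
checked against all previously assigned points by the exact interval
bounds; dead ends backtrack. Two things make this strong enough in
practice:

- **Cross-level backtracking.** A level can be satisfiable in a way that
  makes the *next* level unsatisfiable. Strictly greedy level-by-level
  refinement therefore deadlocks on feasible instances (observed:
  $\varepsilon^*$ inflated 3–4× on 10-point instances). The engine treats
  the whole bit hierarchy as one search tree and backtracks across levels,
  so a fixed-$\varepsilon$ synthesis is decided correctly up to the node
  budget.
- **Restart portfolio with value-ordering hints.** The search first tries a
  geometrically hinted pass — candidate sub-squares ordered by proximity to
  a classical-MDS configuration of the quantized distances — under a
  farthest-point-first assignment order, then pairwise-midpoint-fit passes
  under farthest-point, identity, and six seeded shuffled orders. The hint
  only reorders candidates; every constraint is still checked, so
  soundness is unaffected, and a genuine UNSAT from any single pass is
  conclusive (the pass searched its whole tree). On exactly-embeddable
  inputs the hinted pass succeeds in $d \cdot b/l$ node visits.

The node budget (`node_budget`, default $5\times10^5$ split across the
portfolio) caps worst-case time; exhaustion is reported as `"budget"`,
distinct from `"unsat"`. Symmetry is reduced by restricting the first
assigned point's first block to the lower half of each axis — valid because
reflecting any axis of the grid preserves all pairwise distances.

The per-level decision problem is also exportable as a standard SMT-LIB 2
(QF_BV) query (`encode_refinement_smtlib()`), so a conformant bit-vector
solver can be swapped in as the backend; the built-in procedure is the
default and requires no external software. The per-level selection
constraint as printed elsewhere applies both band bounds to the *maximum*
reachable squared distance; `solve_refinement_step(rule = "literal")` keeps
that reading available, but the default intersects the reachable interval
with the band, because the literal rule can accept a sub-square whose every
completion violates the lower bound — contradicting the refinement's
purpose. At the final level the two coincide.

## Evaluation conventions

Distortion reports compare high-dimensional distances (configured metric,
Manhattan by default) against low-dimensional *Euclidean* distances by
default: Euclidean is what the synthesis band controls, what classical MDS
produces, and what the eye reads off a scatter plot. Feeding Manhattan
high-dimensional distances to a Euclidean 2D embedding is a modeling
mismatch inherited from the problem setup; it is applied identically to all
three methods, and `project_all_points()` records a note when Manhattan
anchors drive Euclidean trilateration. Classical MDS is Torgerson scaling
(double-center, top-$k$ eigenpairs, $\sqrt{\lambda}$ scaling) with signs
fixed by making each axis's largest-magnitude loading positive; random
projection is the Gaussian Johnson–Lindenstrauss construction scaled by
$1/\sqrt{k}$. Ratio tables use truncation (not rounding) to 3 decimals per
row and 2 for summaries — the convention the published benchmark tables
follow, verified against their printed ratio column.

## What the synthetic generator does and does not emulate

`generate_flow_like_cloud()` draws from a Gaussian mixture, clipped at zero
(instrument floor), with per-population means on a raw 0–1000 intensity
scale (drawn once per instance seed from $U(100, 900)$ per channel, 3
populations, spread 50 by default) and an optional rare population below 5%
weight. This reproduces the features the pipeline depends on — separated
multi-population structure in ~12 channels, non-negative intensities,
occasional outlier cells — and deliberately not the features it does not:
no spectral spillover or compensation artifacts, no log-normal/bimodal
marker shapes, no doublets or debris, no acquisition drift. Passing tests
on these clouds demonstrates the algorithmic claims (recovery, band
contracts, distortion ordering against baselines); they say nothing about
gating-grade fidelity on instrument data.

`sample_benchmark_instance()` reproduces the published experimental unit —
10 events in 12 channels per dataset — and `brute_force_min_max_distortion()`
provides an exhaustive oracle on instances small enough to enumerate
($d \le 4$, $b \le 3$, 2D; reflection symmetry and branch-and-bound pruning
keep it under a second). The oracle minimizes the maximum *additive*
distortion, the reported statistic.

## Numerical choices and degenerate inputs

- Quantization: $scale = (2^b-1)/\max D$; rounding error per distance is at
  most $0.5$ grid units, and a planar configuration rounded to the grid
  moves any pairwise distance by at most $\sqrt{2}$ grid units — the
  yardstick for "recovered to quantization".
- Duplicated structural points (padded communities) have target distance 0;
  the band forces them to co-locate, which the interval constraints achieve
  exactly.
- All-zero distance matrices are rejected (nothing to scale); negative
  thresholds, non-finite intensities, and length mismatches fail fast with
  the offending location named.
- Degenerate anchor geometry in placement falls back as described above
  rather than producing NaNs.
- Band checks use an absolute slack of $10^{-9}$ on squared grid distances
  to absorb double rounding; grid arithmetic itself is exact in doubles for
  $b \le 14$.

## Problem sizes in the shipped tests

The test suite exercises the band contract on 50 randomized instances
($d \le 8$, $b \in \{6,8,10\}$), the exhaustive-oracle comparison on 20
instances ($d \le 4$, $b = 3$), sub-square bound soundness on 1000 random
partial configurations ($r \le 3$), head-to-head against MDS on 10
benchmark-shaped instances ($b = 10$, $l = 2$), and pipeline recovery on one
1000-cell 3-population cloud — sizes chosen so the whole suite settles in
about a minute on one core while still covering every contract at
non-trivial scale.

## Known limitations

- Synthesis cost grows quickly with the structural point count; beyond
  $d \approx 30$–40 the node budget, not the mathematics, decides. The
  community skeleton exists precisely to keep $d$ small.
- The additive $\varepsilon^*$ is optimal only up to bisection tolerance and
  the node budget; reported distortions are always measured post hoc, never
  inferred from $\varepsilon$.
- Grid coordinates mean the output is equivariant to neither rotation nor
  sub-grid translation; two runs can return different but equally valid
  embeddings (seeded, they return the same one).
- Threshold selection scans the full pairwise distance matrix
  ($O(N^2)$ memory); beyond ~10⁴ cells subsample first (`sample_size`).
- Walktrap is run single-threaded through igraph; very large networks are
  out of scope here.
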