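# sanjay

Decision-procedure synthesis of low-distortion 2D/3D embeddings of
high-dimensional flow cytometry data.

## The problem

Polychromatic flow cytometry measures ten or more fluorescence channels per
cell, and a sample easily yields 10^5–10^6 events. Humans cannot inspect a
12-dimensional point cloud, and plotting every channel pair scatters the
structure across dozens of panels. The standard remedy — project to 2D while
approximately preserving pairwise distances — is usually attacked with
multidimensional scaling (MDS) or random projections, both of which can
distort individual pairs badly even when they do well on average. For
cytometry that matters: a small cluster of abnormal cells is exactly the
kind of detail a bad worst-case pair can smear away.

This package takes a different route: it *synthesizes* the embedding with a
bit-vector decision procedure. Coordinates are unsigned `b`-bit integers on a
grid; the synthesis fixes `l` high-order bits per coordinate per iteration,
and each iteration is a decision problem — does an assignment of the next
bit blocks exist such that every pair's reachable squared distance still
meets the tolerance band

- multiplicative band: `(1 − ε)·D²ᵢⱼ ≤ ‖Rᵢ − Rⱼ‖² ≤ (1 + ε)·D²ᵢⱼ`, or
- additive band: `| ‖Rᵢ − Rⱼ‖ − Dᵢⱼ | ≤ ε·max(D)`

for quantized target distances `D` (closed-form reachable-interval bounds per
sub-square)? After `b/l` iterations every coordinate is fully determined and
the band holds exactly for all pairs. The smallest feasible `ε` is found by
bisection; with the additive band that minimum *is* the worst-pair additive
distortion, the statistic the method is judged by (Definition:
`distortion(x, y) = |d(x′, y′) − d(x, y)|`).

Because synthesizing all N cells this way is intractable, the pipeline first
compresses the sample into a structural skeleton:

1. **T-FCN** — a network over cells with an edge when Manhattan distance ≤ T,
   with T chosen to maximize the entropy of a topological-property
   distribution (component sizes by default);
2. **communities** — Walktrap random-walk agglomeration partitions the
   network into communities C₁..Cₙ;
3. **structural points** — each community is summarized by its centroid Oᵢ
   plus k-means component centroids Eᵢ¹..Eᵢᵏ (k = 3 for 2D, 4 for 3D), giving
   d = 4n (2D) or 5n (3D) points Q₁..Q_d;
4. **synthesis** — the decision procedure embeds Q₁..Q_d as grid points
   R₁..R_d;
5. **placement** — every remaining cell is positioned by least-squares
   trilateration against its own community's embedded component centroids
   (distances to 3 points fix a 2D position, to 4 points a 3D one).

Baselines (classical Torgerson MDS, Gaussian random projections), per-pair
distortion reports and the published 30-dataset benchmark summary tables are
included for evaluation.

## Worked example

```r
library(sanjay)
cells <- generate_flow_like_cloud(500, m = 12, seed = 42)  # 3 populations
fit <- sanjay_embed(cells, target_dim = 2, bits = 10, seed = 42)
fit
#> synthesized embedding: 500 cells -> 2D, T = 544.11, 7 communities,
#>   d = 28 structural points, epsilon = 0.175
glance(fit)
#> # A tibble: 1 × 9
#>   n_cells target_dim threshold n_communities d_structural epsilon_used scale
#> 1     500          2      544.             7           28        0.175 0.297
#> # max_distortion, avg_distortion
head(tidy(fit), 4)
#> # A tibble: 4 × 6
#>    cell community     x      y x_data y_data
#> 1     1         1 1374. 1081.   4622.  3637.
#> 2     2         3 -262. 1055.   -883.  3551.
#> 3     3         2 -170.   83.2  -572.   280.
#> 4     4         1  570.  653.   1918.  2197.
autoplot(fit)  # ggplot scatter: cells by community, structural anchors marked
```

The threshold 544 (Manhattan units) is the entropy-maximizing network scale;
the 500 cells collapse to 28 structural points (7 communities × 4), which the
decision procedure embeds at ε = 0.175 (additive band, i.e. every structural
pair's distance is preserved within 17.5% of the largest pairwise distance on
the grid); `x`/`y` are grid units, `x_data`/`y_data` the same coordinates
rescaled to intensity units (`scale` = 0.297 grid units per intensity unit).

Head-to-head on one 10-event subsample (the published comparison protocol):

```r
compare_methods(cells, sample_size = 10, seed = 42)
#> # A tibble: 3 × 5
#>   dataset_id method max_distortion avg_distortion ratio_vs_sanjay
#> 1          1 sanjay           349.           95.1           NA
#> 2          1 mds              513.           95.1            1.47
#> 3          1 rp              3276.         1783.             9.39
```

The synthesis's maximum pairwise distortion (349 intensity units) is 1.47×
smaller than MDS's and 9.4× smaller than random projections' on this sample —
the direction and magnitude the published benchmark tables report (mean
MDS/synthesis max-distortion ratio 2.56 over 30 datasets).

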