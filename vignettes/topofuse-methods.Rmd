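---
title: "Feature-topology fusion clustering: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-topology fusion clustering: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofuse)
```

## The problem

Cohorts in complex-disease studies increasingly carry several data layers
per patient: a phenome table of clinical variables (binary, ordinal,
categorical and continuous), plus one or more expression matrices (mRNA,
miRNA, ...). Model-based integrative clustering methods assume continuous
measurements and particular distributions; clinical tables violate both, and
missing values are the rule. `topofuse` implements a model-free alternative:
convert each patient's concatenated feature vector into a smoothed
two-dimensional intensity surface over a shared embedding of all features
("feature topology"), cluster patients on the similarity of these surfaces,
and combine data layers only when they demonstrably tell the same story.

## The pipeline

Let $X^{(m)} = \{x_{ij}^{(m)}\}$ be the $m$-th source (features $i \in I_m$,
patients $j \in J$), already normalized upstream.

1. **Filtering.** Per source, continuous features below the `mean_q`
   quantile of feature means ("non-expressed") and then below the `sd_q`
   quantile of remaining SDs ("non-informative") are dropped; constants of
   any type always are. Non-continuous features are exempt from the
   quantile stages: a rare binary symptom is informative despite a low mean.
2. **Standardization.** Continuous, ordinal and binary features are scaled
   to mean 0, SD 1 (sample SD, $n-1$ denominator — the package's stated
   convention) so no source dominates. Categorical features stay as integer
   level codes; scaling unordered codes is meaningless and the dissimilarity
   step below treats them separately.
3. **Concatenation and mixed-type dissimilarity.** All sources are stacked
   feature-wise into $X$, and a feature-by-feature correlation matrix $R$ is
   computed with a type-pair dispatch: Pearson for continuous pairs,
   Spearman when either member is ordinal, point-biserial/phi for binary
   pairs (both are Pearson on the level codes), and Cramér's V whenever a
   categorical feature is involved. Cramér's V needs a contingency table, so
   a continuous partner is discretized into quartile bins first. All
   correlations use pairwise-complete observations, so missing cells never
   force imputation. The dissimilarity is $D = (1 - R)/2$: co-varying
   features sit near 0, anti-correlated features near 1, unrelated ones at
   0.5. Two asymmetries are accepted deliberately: Cramér's V is sign-free,
   so categorical pairs live in $[0, 0.5]$; and undefined entries (constant
   features, fewer than 3 complete pairs) are set to 0 — a neutral 0.5
   dissimilarity — because the embedding needs a complete matrix.
4. **Embedding.** Non-metric MDS (Kruskal stress-1, initialized from the
   classical MDS solution so the result is deterministic; 300 iterations,
   tolerance $10^{-6}$) places all features in 2D. Because the embedding is
   computed once on the concatenated matrix, coordinates are comparable
   across sources. Each axis is then min-max rescaled to $[0,1]$ — the
   smoothing grid lives on this unit square. The axis-wise rescaling
   changes the aspect ratio; the `coords_raw` element keeps the
   undistorted configuration for anyone who needs the exact geometry.
5. **Smoothing.** For each patient and source, a thin-plate regression
   spline surface of intensity on the embedded coordinates is fit with
   `mgcv` (basis dimension `basis_k`, default 60, capped at half the
   available features; smoothness chosen by GCV) and evaluated on the
   $(n+1)\times(n+1)$ unit-square lattice (`grid_n`, default $n = 50$,
   giving 2601-point profiles). The resulting vector $c_j^{(m)}$ is the
   numeric content of a feature topology plot. Smoothing pools correlated
   features (which the embedding co-locates) and damps isolated noise
   features. Missing intensities are simply left out of the fit.
6. **Patient clustering.** Patients are compared by
   $D_{jj'} = 1 - \mathrm{cor}(c_j, c_{j'})$ and clustered with
   partitioning around medoids; the cluster count is chosen by the gap
   statistic (below). Cluster-averaged profiles give one representative
   topology image per cluster.
7. **Pairwise integration.** Every pair of source groups is cross-tabulated
   after maximum-weight bipartite matching of their clusters (so the
   "diagonal" does not depend on arbitrary label numbers; with unequal
   cluster counts the unmatched clusters count entirely as off-diagonal).
   A pair is *homogeneous* when at most `homogeneity_max_offdiag` (default
   20 %) of patients fall off the matched diagonal — the default sits
   between the off-diagonal fractions the motivating application treated as
   concordant (≈12 %) and discordant (≈38–47 %). The most concordant
   homogeneous pair is merged (one smooth per patient over the pooled
   features on the shared embedding) and the scan repeats; discordant
   sources are left separate and reported. An adjusted Rand index
   accompanies every comparison.

## PAM with restarts

The SWAP phase of PAM is a single-swap local search. On uniform random toy
instances ($n \le 8$, $K \le 3$) it misses the global optimum in roughly 8 %
of cases — a two-swap move would be required. `pam_cluster()` therefore runs
BUILD + SWAP and `nstart - 1` additional SWAP passes from random medoid
sets (deterministic given `seed`), keeping the best objective; with ten
starts the exhaustive optimum was attained in 200/200 random tiny instances.
Clusters are relabeled by first appearance in sample order so labels do not
depend on internal medoid numbering.

## Gap statistic: dispersion, reference and rule

$W(k)$ is PAM's own criterion — total dissimilarity of samples to their
medoids — under the same $1-\mathrm{cor}$ metric used for clustering, and
$\mathrm{gap}(k) = \overline{\log W^*_k} - \log W(k)$ over $B$ reference
data sets. The scan starts at $k = 1$ so "no structure" is representable.
Two design points deserve explanation because both defaults were chosen
after measuring the obvious alternatives failing:

* **Reference distribution.** For raw feature matrices the classic
  independent-uniform-per-column reference behaves well. Smoothed profile
  vectors, however, are extremely collinear across their grid coordinates;
  independent uniform references destroy that structure, make the reference
  spread unrealistically small, and the gap curve then creeps upward past
  the true $K$ under every dispersion variant we tried. Drawing references
  uniformly in the principal-component rotation of the data (and rotating
  back) — the rotated variant of Tibshirani's proposal — respects the
  collinearity and produces a clean interior gap maximum at the planted
  $K$. The workflow therefore uses `gap_reference = "pca"` for profile
  clustering; `gap_select()` keeps `"uniform"` as its standalone default.
* **Selection rule.** The original one-SE rule ("smallest $k$ with
  $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$") stops at $k = 1$
  whenever the curve is flat before jumping at the true $K$ — which is
  exactly the shape profile clustering produces when $k$ is below the true
  count. The default is therefore the `firstSEmax` rule of
  `cluster::maxSE()` (smallest $k$ within one SE of the first local gap
  maximum); `Tibs2001SEmax` and plain `max` remain available, and
  plateau-shaped curves from raw matrices are better served by
  `Tibs2001SEmax`.

Known limitation: on profiles of a *single* Gaussian blob the gap curve
still drifts upward under either reference, so "no structure" is more
reliably diagnosed on the raw matrix than on its profiles.

## Prediction for new cohorts

`predict_clusters()` freezes the training embedding and medoids: new
patients are smoothed on the trained coordinates (features absent from the
new cohort are dropped; at least half must remain) and assigned to the
cluster of the nearest training medoid under $1-\mathrm{cor}$. Refitting
nothing keeps the training solution intact and makes prediction on the
training samples reproduce the training labels exactly. A validation run —
independent re-clustering of the test cohort — can then be compared to the
predictions by ARI.

## The synthetic-data generator

`simulate_multiomics()` plants $K$ balanced (optionally Dirichlet-skewed)
patient clusters. Each informative feature receives a cluster-mean pattern:
a random permutation of $0, \delta, 2\delta, \dots$ with
$\delta = \texttt{effect\_size} \times \texttt{within\_sd}$, plus Gaussian
within-cluster noise; noise features are plain Gaussians. Non-continuous
features arise by thresholding a latent Gaussian feature at balanced
empirical quantile cut points (binary 0/1, ordinal 1–4, categorical 1–3
codes). Missing cells are inserted uniformly at `missing_rate` with a
guarantee that every row and column keeps one observation.
`homogeneous_pair()` / `heterogeneous_pair()` drive two sources by the same
or by independent partitions. `simulate_cohorts()` draws the
*population-level* parameters (informative set, per-feature cluster
signatures, types) once and then samples independent patient cohorts — the
setting a discovery/prediction/validation scheme requires; fresh seeds in
`simulate_multiomics()` resample the population itself, so cohorts made
that way share no feature signatures and prediction between them is
meaningless by construction.

What the generator does *not* emulate: feature-feature correlation beyond
the shared cluster means, batch effects, heavy-tailed intensities, and
informative missingness. Passing tests on these simulations therefore show
that the machinery recovers planted structure under Gaussian noise and
mixed types — not that it is robust to every artefact of real cohorts.

## Problem sizes used in the test suite

The packaged tests and `scripts/acceptance.R` run the pipeline at reduced
sizes chosen to exercise every stage while keeping the suite quick: cohorts
of 45–90 patients, 30–80 features per source, profile grids of
$n = 8$–$12$ (81–169 points), basis dimensions 15–30, and $B = 10$–$25$ gap
references. The method's defaults (`grid_n = 50`, `basis_k = 60`,
`gap_B = 50`) are intended for application-scale data (hundreds of patients,
thousands of features). With strong planted signal (`effect_size = 3`) the
pipeline recovers the planted $K$ and partition essentially always at these
sizes; the fusion-advantage comparison uses the generator's default
`effect_size = 2` so neither route saturates.

## Other conventions

* Canonical sample order after alignment is lexicographic; sample
  intersection across sources is required and empty intersections are
  errors.
* Categorical levels must arrive as integer codes; `read_omics()` can map
  strings to codes (sorted level order) and logs the mapping.
* Pairwise Kruskal–Wallis p values in `group_summary()` are reported
  unadjusted, matching the usual presentation of cluster summary tables;
  only the biomarker ANOVA is multiplicity-controlled (Bonferroni, default
  cutoff $10^{-10}$).
* The miRNA-style sign flip in `module_discovery()` negates the named
  features before the correlation distance, so inhibitory features join the
  module of their targets instead of forming a mirror module.
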