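Package: topofuse
Title: Feature-Topology Fusion Clustering for Multi-Omics Subtype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative clustering of multiple omics data sources of mixed
    variable types (continuous, ordinal, binary, categorical) for disease
    subtype discovery. Features from all sources are concatenated, a
    mixed-type correlation dissimilarity D = (1 - R)/2 is computed, features
    are embedded in two dimensions by non-metric multidimensional scaling,
    and each patient's feature intensities are smoothed over the embedding
    with a thin-plate regression spline surface to give a feature topology
    profile. Patients are clustered on 1 - correlation of their smoothed
    profiles with partitioning around medoids, the number of clusters is
    chosen by the gap statistic, and omics sources are combined pairwise and
    agglomeratively when their clusterings agree (small off-diagonal mass
    after optimal cluster matching), exposing heterogeneous sources
    otherwise. Includes a synthetic multi-omics generator with planted
    cluster structure, nearest-medoid prediction of cluster membership for
    new cohorts, per-feature one-way ANOVA biomarker selection with
    Bonferroni control, and co-expression module discovery with an optional
    sign flip for inhibitory features such as miRNAs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    MASS,
    mgcv,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
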