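#' Per-feature one-way ANOVA across patient clusters
#'
#' Classic one-way F test of each feature against the cluster labels of the
#' selected samples, with Bonferroni control over all tested features.
#' Degenerate features are handled explicitly: zero between- and
#' within-group variance gives F = 0, p = 1; zero within-group variance with
#' group separation gives F = Inf, p = 0.
#'
#' @param concat A `concat_features` (typically of the expression sources
#'   only) or a single [omics_dataset()].
#' @param labels Named cluster labels; only samples present in `labels` (and
#'   not `NA`) are used, so passing labels restricted to the selected
#'   clusters restricts the test.
#' @param alpha Cutoff on the Bonferroni-adjusted p value.
#' @return A `data.frame` of class `biomarker_result` with columns
#'   `feature_id`, `source`, `F`, `p`, `p_adj`, `significant`, sorted by
#'   `p_adj`.
#' @export
anova_select <- function(concat, labels, alpha = 1e-10) {
  if (inherits(concat, "omics_dataset")) concat <- concatenate_omics(concat)
  labels <- labels[!is.na(labels)]
  use <- intersect(colnames(concat$matrix), names(labels))
  if (length(use) < 4L) stop("too few labeled samples")
  m <- concat$matrix[, use, drop = FALSE]
  g <- factor(labels[use])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need >= 2 clusters with >= 2 members each")
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    oneway_f(m[i, ], g)
  }, numeric(2)))
  p_adj <- pmin(1, res[, 2] * nrow(m))
  out <- data.frame(feature_id = rownames(m), source = concat$origin,
                    F = res[, 1], p = res[, 2], p_adj = p_adj,
                    significant = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p), ]
  rownames(out) <- NULL
  class(out) <- c("biomarker_result", "data.frame")
  out
}

# One-way ANOVA F statistic and p value with explicit degenerate handling.
oneway_f <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || length(x) <= nlevels(g)) return(c(0, 1))
  gm <- tapply(x, g, mean)
  ng <- tapply(x, g, length)
  ssb <- sum(ng * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  dfb <- nlevels(g) - 1L
  dfw <- length(x) - nlevels(g)
  if (ssw == 0 && ssb == 0) return(c(0, 1))
  if (ssw == 0) return(c(Inf, 0))
  f <- (ssb / dfb) / (ssw / dfw)
  c(f, stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

#' Co-expression module discovery with optional sign flip
#'
#' Clusters the selected features by PAM on the 1 - Pearson feature-feature
#' correlation distance, with the module count chosen by the gap statistic.
#' Features in `flip_ids` (typically miRNAs, which are predominantly
#' inhibitory) have their intensities negated before correlation, so a miRNA
#' anti-correlated with its target mRNAs joins their module.
#'
#' @param values Feature x sample numeric matrix of the selected
#'   (significant) features.
#' @param flip_ids Feature ids to negate before clustering.
#' @param g_max Largest module count scanned.
#' @param B,seed,nstart Gap-statistic parameters (see [gap_select()]).
#' @return List with `assignment` (data frame `feature_id`, `module`,
#'   `sign_flipped`), `solution` (the feature-level `cluster_solution` with
#'   gap curve) and `values` (the sign-flipped matrix actually clustered).
#' @export
module_discovery <- function(values, flip_ids = character(), g_max = 6L,
                             B = 50L, seed = 1L, nstart = 5L) {
  stopifnot(is.matrix(values))
  if (nrow(values) < 2L) stop("need at least 2 features to form modules")
  flipped <- rownames(values) %in% flip_ids
  v <- values
  v[flipped, ] <- -v[flipped, ]
  sol <- gap_select(v, k_max = g_max, B = B, seed = seed, nstart = nstart,
                    source = "features")
  list(assignment = data.frame(feature_id = rownames(values),
                               module = unname(sol$labels[rownames(values)]),
                               sign_flipped = flipped,
                               stringsAsFactors = FALSE),
       solution = sol, values = v)
}

#' Cluster-wise summary of clinical variables
#'
#' For each variable: per-cluster means (binary variables are reported as
#' the percentage of samples in the upper level), a Kruskal-Wallis test
#' across all clusters and pairwise Kruskal-Wallis (rank-sum) tests for
#' every cluster pair. Pairwise p values are reported unadjusted.
#'
#' @param clinical An [omics_dataset()] of clinical variables.
#' @param labels Named cluster labels covering (a subset of) its samples.
#' @return A `data.frame` with one row per variable: `variable`, `type`,
#'   `overall`, one `mean_<k>` column per cluster, `p_kw`, and one
#'   `p_<k1>v<k2>` column per cluster pair. All-missing variables yield an
#'   all-`NA` row.
#' @export
group_summary <- function(clinical, labels) {
  labels <- labels[!is.na(labels)]
  use <- intersect(sample_ids(clinical), names(labels))
  if (!length(use)) stop("labels cover none of the clinical samples")
  v <- clinical$values[use, , drop = FALSE]
  g <- factor(labels[use])
  ks <- levels(g)
  prs <- utils::combn(ks, 2)
  summ_one <- function(x, type) {
    if (all(is.na(x)))
      return(rep(NA_real_, 1L + length(ks) + 1L + ncol(prs)))
    if (type == "binary") {
      lev <- sort(unique(x[!is.na(x)]))
      x_num <- as.numeric(x == lev[length(lev)]) * 100
    } else x_num <- x
    means <- c(mean(x_num, na.rm = TRUE),
               tapply(x_num, g, mean, na.rm = TRUE))
    p_kw <- tryCatch(stats::kruskal.test(x, g)$p.value, error = function(e) NA_real_)
    p_pair <- apply(prs, 2, function(pr) {
      sel <- g %in% pr
      tryCatch(stats::kruskal.test(x[sel], droplevels(g[sel]))$p.value,
               error = function(e) NA_real_)
    })
    c(means, p_kw, p_pair)
  }
  rows <- t(vapply(seq_len(ncol(v)), function(j)
    summ_one(v[, j], clinical$var_types[j]),
    numeric(1L + length(ks) + 1L + ncol(prs))))
  out <- data.frame(variable = colnames(v),
                    type = unname(clinical$var_types), rows,
                    row.names = NULL, stringsAsFactors = FALSE)
  colnames(out)[-(1:2)] <- c("overall", paste0("mean_", ks), "p_kw",
                             paste0("p_", prs[1, ], "v", prs[2, ]))
  out
}

#' Export a module-by-cluster heatmap matrix
#'
#' Reorders the selected features by module and the samples by cluster,
#' applies the sign flip, writes the resulting matrix as TSV (with module,
#' flip and cluster annotations) and optionally renders a heatmap.
#'
#' @param values Feature x sample matrix (unflipped).
#' @param assignment Module assignment data frame from [module_discovery()].
#' @param labels Named cluster labels for the samples.
#' @param path TSV output path, or `NULL` to skip writing.
#' @param plot_file Optional `.png`/`.pdf` path; rendered with
#'   \pkg{pheatmap} when installed, otherwise with [graphics::image()].
#' @return The reordered, sign-flipped matrix, invisibly, with attributes
#'   `modules` and `clusters`.
#' @export
heatmap_export <- function(values, assignment, labels, path = NULL,
                           plot_file = NULL) {
  stopifnot(all(assignment$feature_id %in% rownames(values)))
  labels <- labels[intersect(colnames(values), names(labels))]
  v <- values[assignment$feature_id, names(labels), drop = FALSE]
  v[assignment$sign_flipped, ] <- -v[assignment$sign_flipped, ]
  ford <- order(assignment$module)
  sord <- order(labels)
  v <- v[ford, sord, drop = FALSE]
  modules <- assignment$module[ford]
  flipped <- assignment$sign_flipped[ford]
  clusters <- labels[sord]
  if (!is.null(path)) {
    df <- data.frame(feature_id = rownames(v), module = modules,
                     sign_flipped = flipped, v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = colnames(v), cluster = unname(clusters)),
      sub("(\\.[^.]*)?$", ".clusters.tsv", path, perl = TRUE)[1],
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(plot_file)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      ann_r <- data.frame(module = factor(modules),
                          flipped = factor(flipped),
                          row.names = rownames(v))
      ann_c <- data.frame(cluster = factor(clusters),
                          row.names = colnames(v))
      pheatmap::pheatmap(v, cluster_rows = FALSE, cluster_cols = FALSE,
                         annotation_row = ann_r, annotation_col = ann_c,
                         show_colnames = FALSE, filename = plot_file)
    } else {
      if (grepl("\\.png$", plot_file)) grDevices::png(plot_file, 800, 800)
      else grDevices::pdf(plot_file, 8, 8)
      graphics::image(t(v)[, rev(seq_len(nrow(v)))], axes = FALSE,
                      main = "modules x clusters")
      grDevices::dev.off()
    }
  }
  attr(v, "modules") <- modules
  attr(v, "clusters") <- clusters
  invisible(v)
}
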