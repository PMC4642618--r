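#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table under the permutation model: 1 for identical partitions, about 0
#' for independent ones. When the adjustment denominator is 0 (degenerate
#' marginals, e.g. a single cluster against anything), the index is defined
#' as 1 if every sample pair agrees between the two partitions and 0
#' otherwise.
#'
#' @param labels1,labels2 Equal-length cluster label vectors (any atomic
#'   type); names are ignored, positions must correspond.
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("label vectors differ in length (", length(labels1), " vs ",
         length(labels2), ")")
  tab <- table(labels1, labels2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  exp_ij <- a * b / choose(n, 2)
  max_ij <- (a + b) / 2
  if (abs(max_ij - exp_ij) < .Machine$double.eps * n^2) {
    agree <- sum_ij - exp_ij
    disagree_possible <- a + b - 2 * sum_ij
    return(as.numeric(disagree_possible == 0))
  }
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

# All permutations of 1..n as a matrix with one permutation per row.
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# Maximum total count over injective matchings of the smaller dimension of
# `tab` into the larger; returns the matched mass.
best_matching_mass <- function(tab) {
  r <- nrow(tab); c <- ncol(tab)
  if (min(r, c) > 7L)
    stop("optimal matching supports at most 7 clusters on the smaller side")
  if (r <= c) {
    P <- perms(c)
    best <- 0
    for (i in seq_len(nrow(P))) {
      m <- sum(tab[cbind(seq_len(r), P[i, seq_len(r)])])
      if (m > best) best <- m
    }
  } else {
    best <- best_matching_mass(t(tab))
  }
  best
}

#' Cross-tabulate two cluster solutions and measure their agreement
#'
#' Builds the K1 x K2 table of shared patients, aligns the clusters of the
#' two solutions by maximum-weight bipartite matching (so the "diagonal" is
#' well defined regardless of label numbering; with K1 != K2 the unmatched
#' clusters count entirely as off-diagonal), and reports the off-diagonal
#' count and fraction, the adjusted Rand index and a homogeneity verdict.
#'
#' @param sol1,sol2 `cluster_solution` objects (or named label vectors) over
#'   the same samples.
#' @param threshold Largest off-diagonal fraction still called homogeneous.
#' @return Object of class `comparison_report`: list with `table`,
#'   `offdiag_count`, `offdiag_fraction`, `ari`, `verdict`, `sources`.
#' @export
cluster_crosstab <- function(sol1, sol2, threshold = 0.2) {
  l1 <- if (inherits(sol1, "cluster_solution")) sol1$labels else sol1
  l2 <- if (inherits(sol2, "cluster_solution")) sol2$labels else sol2
  if (!is.null(names(l1)) && !is.null(names(l2))) {
    if (!setequal(names(l1), names(l2)))
      stop("solutions cover different samples")
    l2 <- l2[names(l1)]
  } else if (length(l1) != length(l2)) {
    stop("label vectors differ in length")
  }
  tab <- table(cluster1 = l1, cluster2 = l2)
  n <- sum(tab)
  matched <- best_matching_mass(tab)
  off <- n - matched
  report <- structure(list(table = tab,
                           offdiag_count = as.integer(off),
                           offdiag_fraction = off / n,
                           ari = adjusted_rand_index(l1, l2),
                           verdict = NA_character_,
                           sources = list(
                             if (inherits(sol1, "cluster_solution")) sol1$source,
                             if (inherits(sol2, "cluster_solution")) sol2$source)),
                      class = "comparison_report")
  decide_homogeneity(report, threshold)
}

#' @export
print.comparison_report <- function(x, ...) {
  s <- vapply(x$sources, function(z)
    if (is.null(z)) "?" else paste(z, collapse = "+"), "")
  cat("comparison_report: ", s[1], " vs ", s[2], "\n", sep = "")
  print(x$table)
  cat(sprintf("off-diagonal: %d/%d (%.1f%%); ARI = %.3f; verdict: %s\n",
              x$offdiag_count, sum(x$table), 100 * x$offdiag_fraction,
              x$ari, x$verdict))
  invisible(x)
}

#' Homogeneity verdict for a pair of clusterings
#'
#' A pair of omics sources is called homogeneous when at most `threshold` of
#' the shared patients fall off the optimally matched diagonal of the
#' cross-tabulation (boundary included).
#'
#' @param report A `comparison_report`.
#' @param threshold Off-diagonal fraction cutoff (default 0.20).
#' @return The report with `verdict` set to `"homogeneous"` or
#'   `"heterogeneous"`.
#' @export
decide_homogeneity <- function(report, threshold = 0.2) {
  report$verdict <- if (report$offdiag_fraction <= threshold)
    "homogeneous" else "heterogeneous"
  report
}

#' Re-cluster patients on the pooled features of a merged source group
#'
#' Profiles are recomputed by a single smooth per patient over the features
#' of all sources in the group (their MDS coordinates are comparable because
#' the embedding was computed once on the concatenated data), then patients
#' are clustered as usual.
#'
#' @param embedding The shared `feature_embedding`.
#' @param concat The `concat_features` it was computed from.
#' @param group Character vector of source labels to pool.
#' @param config A [run_config()].
#' @return A list with `solution` (a `cluster_solution` labeled with the
#'   merged group) and `profiles`.
#' @export
merge_and_recluster <- function(embedding, concat, group,
                                config = run_config()) {
  profiles <- smooth_profiles(embedding, concat, source = group,
                              grid_n = config$grid_n,
                              basis_k = config$basis_k)
  sol <- gap_select(unclass(profiles), k_max = config$k_max, B = config$gap_B,
                    seed = config$seed, nstart = config$nstart,
                    rule = config$gap_rule, reference = config$gap_reference,
                    source = group)
  list(solution = sol, profiles = profiles)
}

#' Run the full integrative clustering workflow
#'
#' End-to-end pipeline: align samples, filter and standardize each source,
#' concatenate, compute the mixed-type correlation dissimilarity, embed all
#' features by non-metric MDS once, smooth each patient per source, cluster
#' each source (PAM, gap-selected K), then iteratively cross-compare all
#' source groups and merge the most homogeneous pair (smallest off-diagonal
#' fraction at or below the threshold), re-smoothing and re-clustering the
#' merged group, until no pair is mergeable. The comparison reports of the
#' remaining (heterogeneous) group pairs are returned for inspection.
#'
#' @param datasets List of two or more [omics_dataset()] objects.
#' @param config A [run_config()].
#' @param filter Logical; apply [filter_features()] per source (with the
#'   config quantiles) before standardizing.
#' @return Object of class `workflow_result`: list with `merge_plan`
#'   (`merges`: list of merge events; `groups`: final partition of sources),
#'   `solutions` and `profiles` (one per final group, named by the group
#'   label), `final_reports` (pairwise `comparison_report`s of the final
#'   groups), `embedding`, `concat`, `filter_reports`, `config`.
#' @export
run_workflow <- function(datasets, config = run_config(), filter = TRUE) {
  if (length(datasets) < 2L) stop("need at least 2 omics sources")
  datasets <- align_samples(datasets)
  filter_reports <- list()
  if (filter) {
    for (i in seq_along(datasets)) {
      fr <- filter_features(datasets[[i]],
                            mean_q = config$filter_mean_quantile,
                            sd_q = config$filter_sd_quantile)
      datasets[[i]] <- fr$dataset
      filter_reports[[datasets[[i]]$name]] <- fr$report
    }
  }
  datasets <- lapply(datasets, standardize_features)
  concat <- concatenate_omics(datasets)
  embedding <- embed_concat(concat, maxit = config$mds_maxit,
                            tol = config$mds_tol)

  groups <- lapply(datasets, function(ds) ds$name)
  fits <- lapply(groups, function(g)
    merge_and_recluster(embedding, concat, g, config))
  merges <- list()

  repeat {
    if (length(groups) < 2L) break
    pairs <- utils::combn(length(groups), 2)
    reports <- apply(pairs, 2, function(ij)
      cluster_crosstab(fits[[ij[1]]]$solution, fits[[ij[2]]]$solution,
                       threshold = config$homogeneity_max_offdiag),
      simplify = FALSE)
    offs <- vapply(reports, `[[`, 0, "offdiag_fraction")
    best <- which.min(offs)
    if (reports[[best]]$verdict != "homogeneous") break
    ij <- pairs[, best]
    new_group <- c(groups[[ij[1]]], groups[[ij[2]]])
    merges[[length(merges) + 1L]] <- list(merged = new_group,
                                          report = reports[[best]])
    groups <- c(groups[-ij], list(new_group))
    fits <- c(fits[-ij],
              list(merge_and_recluster(embedding, concat, new_group, config)))
  }

  final_reports <- list()
  if (length(groups) >= 2L) {
    pairs <- utils::combn(length(groups), 2)
    final_reports <- apply(pairs, 2, function(ij)
      cluster_crosstab(fits[[ij[1]]]$solution, fits[[ij[2]]]$solution,
                       threshold = config$homogeneity_max_offdiag),
      simplify = FALSE)
  }
  nm <- vapply(groups, paste, "", collapse = "+")
  solutions <- stats::setNames(lapply(fits, `[[`, "solution"), nm)
  profiles <- stats::setNames(lapply(fits, `[[`, "profiles"), nm)
  structure(list(merge_plan = list(merges = merges, groups = groups),
                 solutions = solutions, profiles = profiles,
                 final_reports = final_reports, embedding = embedding,
                 concat = concat, filter_reports = filter_reports,
                 config = config),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("workflow_result:", length(x$merge_plan$merges), "merge(s); final groups:",
      paste(vapply(x$merge_plan$groups, paste, "", collapse = "+"),
            collapse = ", "), "\n")
  for (nm in names(x$solutions)) print(x$solutions[[nm]])
  invisible(x)
}

#' Freeze a trained model for cluster prediction on a new cohort
#'
#' @param embedding The training `feature_embedding` (computed on the
#'   training cohort's concatenated features).
#' @param profiles The training `smoothed_profiles` of the source group.
#' @param solution The training `cluster_solution`.
#' @param basis_k Basis dimension used for smoothing.
#' @return Object of class `trained_model`.
#' @export
trained_model <- function(embedding, profiles, solution, basis_k = 60L) {
  structure(list(embedding = embedding, profiles = profiles,
                 solution = solution, grid_n = attr(profiles, "grid_n"),
                 source = attr(profiles, "source"), basis_k = basis_k),
            class = "trained_model")
}

#' Predict cluster membership for new patients
#'
#' The training MDS coordinates are frozen and applied directly to the new
#' cohort: each new patient's intensities over the shared features are
#' smoothed on the training embedding, and the patient is assigned to the
#' cluster of the nearest training medoid under the 1 - correlation profile
#' dissimilarity. Features absent from the new cohort are dropped from the
#' smooth; at least half of the training features must be present.
#'
#' @param trained A [trained_model()].
#' @param new_dataset An [omics_dataset()] (or list of datasets, concatenated
#'   internally) for the new cohort; standardized internally
#'   (standardization is idempotent, so already-standardized input is safe).
#' @return Named integer vector of predicted cluster labels.
#' @export
predict_clusters <- function(trained, new_dataset) {
  stopifnot(inherits(trained, "trained_model"))
  if (inherits(new_dataset, "omics_dataset")) new_dataset <- list(new_dataset)
  new_dataset <- lapply(new_dataset, standardize_features)
  concat <- concatenate_omics(new_dataset)
  train_feats <- rownames(trained$embedding$coords)
  if (!is.null(trained$embedding$origin)) {
    keep <- trained$embedding$origin %in% trained$source
    if (any(keep)) train_feats <- train_feats[keep]
  }
  common <- intersect(train_feats, rownames(concat$matrix))
  if (length(common) < 0.5 * length(train_feats))
    stop("only ", length(common), "/", length(train_feats),
         " training features present in the new cohort (< 50%)")
  m <- concat$matrix[common, , drop = FALSE]
  new_profiles <- t(vapply(seq_len(ncol(m)), function(j)
    smooth_patient(trained$embedding, stats::setNames(m[, j], common),
                   grid_n = trained$grid_n, features = common,
                   basis_k = trained$basis_k),
    numeric((trained$grid_n + 1L)^2)))
  rownames(new_profiles) <- colnames(m)
  med_prof <- unclass(trained$profiles)[trained$solution$medoid_ids, ,
                                        drop = FALSE]
  d <- 1 - suppressWarnings(stats::cor(t(new_profiles), t(med_prof)))
  d[is.na(d)] <- 1
  lab <- apply(d, 1, which.min)
  med_lab <- trained$solution$labels[trained$solution$medoid_ids]
  stats::setNames(as.integer(med_lab[lab]), rownames(new_profiles))
}
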