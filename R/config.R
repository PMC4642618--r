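#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults are suitable for
#' expression-scale omics; see the methods vignette for the reasoning behind
#' each.
#'
#' @param grid_n Grid resolution n of the smoothed profiles: each patient
#'   profile is evaluated on the (n+1) x (n+1) unit-square lattice, giving a
#'   vector of length (n+1)^2. Minimum 8.
#' @param k_max Largest cluster count scanned by the gap statistic.
#' @param gap_B Number of uniform reference data sets for the gap statistic
#'   (minimum 10).
#' @param filter_mean_quantile,filter_sd_quantile Quantile cutoffs for the
#'   low-mean / low-SD feature filters, in \[0, 1).
#' @param homogeneity_max_offdiag Largest off-diagonal fraction of an
#'   optimally matched cross-tabulation still called "homogeneous".
#' @param anova_alpha Bonferroni-adjusted p cutoff for biomarker selection.
#' @param seed Integer seed controlling every stochastic step.
#' @param nstart Number of PAM starts (BUILD plus `nstart - 1` random
#'   restarts; the best objective wins).
#' @param basis_k Requested thin-plate basis dimension for patient smoothing;
#'   capped at half the available feature count.
#' @param mds_maxit,mds_tol Iteration cap and stress tolerance for the
#'   non-metric MDS stress minimization.
#' @param gap_rule Gap K-selection rule: `"firstSEmax"` (default; smallest k
#'   within one standard error of the first local gap maximum),
#'   `"Tibs2001SEmax"` (the original one-SE rule) or `"max"` (global gap
#'   maximum). See [gap_select()].
#' @param gap_reference Reference distribution for the gap statistic when
#'   clustering smoothed profiles: `"pca"` (default; uniform in the
#'   principal-component rotation, which respects the strong collinearity of
#'   profile grid coordinates) or `"uniform"` (independent uniform per
#'   coordinate).
#' @return A list of class `tf_config`.
#' @export
run_config <- function(grid_n = 50L, k_max = 6L, gap_B = 50L,
                       filter_mean_quantile = 0.3, filter_sd_quantile = 0.3,
                       homogeneity_max_offdiag = 0.2, anova_alpha = 1e-10,
                       seed = 1L, nstart = 5L, basis_k = 60L,
                       mds_maxit = 300L, mds_tol = 1e-6,
                       gap_rule = c("firstSEmax", "Tibs2001SEmax", "max"),
                       gap_reference = c("pca", "uniform")) {
  cfg <- list(grid_n = as.integer(grid_n), k_max = as.integer(k_max),
              gap_B = as.integer(gap_B),
              filter_mean_quantile = filter_mean_quantile,
              filter_sd_quantile = filter_sd_quantile,
              homogeneity_max_offdiag = homogeneity_max_offdiag,
              anova_alpha = anova_alpha, seed = as.integer(seed),
              nstart = as.integer(nstart), basis_k = as.integer(basis_k),
              mds_maxit = as.integer(mds_maxit), mds_tol = mds_tol,
              gap_rule = match.arg(gap_rule),
              gap_reference = match.arg(gap_reference))
  stopifnot(cfg$grid_n >= 8L, cfg$k_max >= 2L, cfg$gap_B >= 10L,
            cfg$nstart >= 1L, cfg$basis_k >= 3L, cfg$mds_maxit >= 1L)
  for (f in c("filter_mean_quantile", "filter_sd_quantile",
              "homogeneity_max_offdiag"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must be in [0, 1]")
  if (cfg$anova_alpha <= 0 || cfg$anova_alpha > 1)
    stop("'anova_alpha' must be in (0, 1]")
  structure(cfg, class = "tf_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `tf_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' @export
print.tf_config <- function(x, ...) {
  cat("topofuse run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
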