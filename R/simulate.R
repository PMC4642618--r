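#' Specify a synthetic multi-omics simulation
#'
#' Defines a cohort with `k_true` latent patient clusters measured on one or
#' more omics sources. Informative features carry cluster-specific means
#' separated by `effect_size` within-cluster standard deviations; the
#' remaining features are pure noise from a single distribution. Phenome-like
#' sources mix variable types: non-continuous features are produced by
#' thresholding a latent Gaussian feature at balanced quantile cut points.
#'
#' @param n_samples Number of patients.
#' @param k_true Number of latent clusters (>= 1).
#' @param omics_specs List of per-source specs, each a list with elements
#'   `n_features`, optional `name`, optional `var_type_mix` (named proportions
#'   over `continuous`/`ordinal`/`binary`/`categorical`; default all
#'   continuous), optional `n_informative` (default
#'   `round((1 - noise_fraction) * n_features)`).
#' @param effect_size Separation between adjacent cluster centroids, in units
#'   of `within_sd`.
#' @param within_sd Within-cluster standard deviation of informative features.
#' @param noise_fraction Default fraction of features with no cluster signal.
#' @param missing_rate Fraction of cells set to `NA`, uniformly at random
#'   (each sample and feature is guaranteed to keep at least one observed
#'   value).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param balanced If `TRUE` cluster sizes are as equal as possible;
#'   otherwise sizes are drawn from a symmetric Dirichlet with concentration
#'   `dirichlet_alpha`.
#' @param dirichlet_alpha Concentration for skewed cluster sizes.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_samples, k_true, omics_specs, effect_size = 2,
                     within_sd = 1, noise_fraction = 0.5, missing_rate = 0,
                     seed = 1L, balanced = TRUE, dirichlet_alpha = 2) {
  stopifnot(k_true >= 1, n_samples >= 1, length(omics_specs) >= 1,
            noise_fraction >= 0, noise_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1, within_sd > 0,
            effect_size >= 0)
  if (k_true > n_samples) stop("k_true cannot exceed n_samples")
  omics_specs <- lapply(seq_along(omics_specs), function(m) {
    os <- omics_specs[[m]]
    if (is.null(os$name)) os$name <- paste0("omics", m)
    if (is.null(os$var_type_mix)) os$var_type_mix <- c(continuous = 1)
    if (is.null(os$n_informative))
      os$n_informative <- round((1 - noise_fraction) * os$n_features)
    if (os$n_informative > os$n_features)
      stop("n_informative exceeds n_features for source '", os$name, "'")
    bad <- setdiff(names(os$var_type_mix), VAR_TYPES)
    if (length(bad)) stop("unknown var type in mix: ", paste(bad, collapse = ", "))
    os
  })
  structure(list(n_samples = as.integer(n_samples),
                 k_true = as.integer(k_true), omics_specs = omics_specs,
                 effect_size = effect_size, within_sd = within_sd,
                 noise_fraction = noise_fraction, missing_rate = missing_rate,
                 seed = as.integer(seed), balanced = balanced,
                 dirichlet_alpha = dirichlet_alpha),
            class = "sim_spec")
}

# Balanced (or Dirichlet-skewed) cluster labels for n samples.
draw_labels <- function(n, k, balanced, alpha) {
  if (balanced) {
    lab <- rep_len(seq_len(k), n)
  } else {
    w <- stats::rgamma(k, shape = alpha)
    lab <- sample.int(k, n, replace = TRUE, prob = w / sum(w))
    while (length(unique(lab)) < k)          # every cluster non-empty
      lab[sample.int(n, 1)] <- setdiff(seq_len(k), unique(lab))[1]
  }
  sample(lab)                                 # random order
}

# Number of level codes used when discretizing a latent Gaussian feature.
N_LEVELS <- c(binary = 2L, ordinal = 4L, categorical = 3L)

discretize_latent <- function(x, type) {
  L <- N_LEVELS[[type]]
  cuts <- stats::quantile(x, probs = seq_len(L - 1) / L, names = FALSE)
  codes <- findInterval(x, cuts) + 1L          # 1..L
  if (type == "binary") codes - 1L else codes  # binary coded 0/1
}

# Population-level parameters of one source: which features carry signal,
# each informative feature's cluster-mean pattern (a permutation of
# 0..K-1 level steps), and the per-feature variable types. Drawing these
# once and reusing them across cohorts is what makes train/test cohorts
# come from the same population.
source_params <- function(os, K) {
  p <- os$n_features
  informative <- rep(FALSE, p)
  informative[sample.int(p, os$n_informative)] <- TRUE
  pattern <- matrix(NA_integer_, K, p)
  for (j in which(informative)) pattern[, j] <- sample.int(K) - 1L
  mix <- os$var_type_mix / sum(os$var_type_mix)
  counts <- stats::setNames(integer(length(VAR_TYPES)), VAR_TYPES)
  counts[names(mix)] <- floor(mix * p)
  while (sum(counts) < p) {                    # largest-remainder top-up
    fr <- mix * p - counts[names(mix)]
    counts[names(mix)[which.max(fr)]] <- counts[names(mix)[which.max(fr)]] + 1L
  }
  list(informative = informative, pattern = pattern,
       types = sample(rep(VAR_TYPES, counts)))
}

# Realize one cohort of one source from its population parameters.
realize_source <- function(os, par, lab, spec, sample_names) {
  n <- length(lab); p <- os$n_features
  delta <- spec$effect_size * spec$within_sd
  vals <- matrix(stats::rnorm(n * p, 0, spec$within_sd), n, p)
  for (j in which(par$informative))
    vals[, j] <- vals[, j] + delta * par$pattern[lab, j]
  for (j in which(par$types != "continuous"))
    vals[, j] <- discretize_latent(vals[, j], par$types[j])
  if (spec$missing_rate > 0) {
    idx <- which(stats::runif(n * p) < spec$missing_rate)
    vals[idx] <- NA_real_
    for (i in which(rowSums(!is.na(vals)) == 0))
      vals[i, sample.int(p, 1)] <- stats::rnorm(1, 0, spec$within_sd)
    for (j in which(colSums(!is.na(vals)) == 0))
      vals[sample.int(n, 1), j] <- stats::rnorm(1, 0, spec$within_sd)
  }
  dimnames(vals) <- list(sample_names, paste0(os$name, "_f", seq_len(p)))
  list(ds = omics_dataset(vals, var_types = par$types, name = os$name),
       mask = stats::setNames(par$informative, colnames(vals)))
}

simulate_source <- function(os, lab, spec, sample_names) {
  realize_source(os, source_params(os, max(lab)), lab, spec, sample_names)
}

#' Generate a synthetic multi-omics cohort with known cluster structure
#'
#' All sources are driven by the same latent patient partition (see
#' [heterogeneous_pair()] for discordant sources). Reproducible from
#' `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `sim_result` with elements `datasets` (list of
#'   [omics_dataset()]), `true_labels` (named integer vector),
#'   `labels_by_omics` (per-source driving labels) and `informative_mask`
#'   (per-source named logical vectors).
#' @export
simulate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_names <- sprintf("s%03d", seq_len(n))
  lab <- stats::setNames(draw_labels(n, spec$k_true, spec$balanced,
                                     spec$dirichlet_alpha), sample_names)
  out <- lapply(spec$omics_specs, simulate_source, lab = lab, spec = spec,
                sample_names = sample_names)
  structure(list(datasets = lapply(out, `[[`, "ds"),
                 true_labels = lab,
                 labels_by_omics = rep(list(lab), length(out)),
                 informative_mask = lapply(out, `[[`, "mask"),
                 spec = spec),
            class = "sim_result")
}

#' Concordant and discordant two-source simulations
#'
#' `homogeneous_pair()` returns two omics sources driven by the same latent
#' patient partition, so their independent clusterings should agree.
#' `heterogeneous_pair()` draws a second, independent partition for the second
#' source, so the cross-tabulation of the two clusterings carries large
#' off-diagonal mass and the pair must not be merged.
#'
#' @param spec A [sim_spec()]; if only one source spec is given it is used for
#'   both members of the pair.
#' @return A `sim_result` (see [simulate_multiomics()]); for the
#'   heterogeneous case `labels_by_omics` differ between the two sources and
#'   `true_labels` are those driving the first source.
#' @export
homogeneous_pair <- function(spec) {
  spec <- pair_spec(spec)
  simulate_multiomics(spec)
}

#' @rdname homogeneous_pair
#' @export
heterogeneous_pair <- function(spec) {
  spec <- pair_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_names <- sprintf("s%03d", seq_len(n))
  lab1 <- stats::setNames(draw_labels(n, spec$k_true, spec$balanced,
                                      spec$dirichlet_alpha), sample_names)
  lab2 <- stats::setNames(draw_labels(n, spec$k_true, spec$balanced,
                                      spec$dirichlet_alpha), sample_names)
  out1 <- simulate_source(spec$omics_specs[[1]], lab1, spec, sample_names)
  out2 <- simulate_source(spec$omics_specs[[2]], lab2, spec, sample_names)
  structure(list(datasets = list(out1$ds, out2$ds),
                 true_labels = lab1,
                 labels_by_omics = list(lab1, lab2),
                 informative_mask = list(out1$mask, out2$mask),
                 spec = spec),
            class = "sim_result")
}

#' Simulate several patient cohorts from one population
#'
#' Draws the population-level parameters (informative features, their
#' cluster-mean signatures, variable types) once, then samples each cohort's
#' patients independently. Because the feature signatures are shared,
#' cluster k means the same thing in every cohort — the setting required by
#' a discovery/prediction/validation scheme, where a model trained on one
#' cohort is applied to another.
#'
#' @param spec A [sim_spec()]; `spec$n_samples` is the size of each cohort
#'   unless `cohort_sizes` is given.
#' @param cohort_sizes Integer vector of cohort sizes (its length sets the
#'   number of cohorts; default two cohorts of `spec$n_samples`).
#' @return A list of `sim_result` objects (one per cohort, sample ids
#'   prefixed `c<i>_`), sharing `informative_mask`.
#' @export
simulate_cohorts <- function(spec,
                             cohort_sizes = rep(spec$n_samples, 2L)) {
  stopifnot(inherits(spec, "sim_spec"), length(cohort_sizes) >= 1L,
            all(cohort_sizes >= spec$k_true))
  set.seed(spec$seed)
  params <- lapply(spec$omics_specs, source_params, K = spec$k_true)
  lapply(seq_along(cohort_sizes), function(ci) {
    n <- cohort_sizes[ci]
    sample_names <- sprintf("c%d_s%03d", ci, seq_len(n))
    lab <- stats::setNames(draw_labels(n, spec$k_true, spec$balanced,
                                       spec$dirichlet_alpha), sample_names)
    out <- lapply(seq_along(spec$omics_specs), function(m)
      realize_source(spec$omics_specs[[m]], params[[m]], lab, spec,
                     sample_names))
    structure(list(datasets = lapply(out, `[[`, "ds"),
                   true_labels = lab,
                   labels_by_omics = rep(list(lab), length(out)),
                   informative_mask = lapply(out, `[[`, "mask"),
                   spec = spec),
              class = "sim_result")
  })
}

pair_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (length(spec$omics_specs) == 1L) {
    os2 <- spec$omics_specs[[1]]
    os2$name <- paste0(os2$name, "b")
    spec$omics_specs <- list(spec$omics_specs[[1]], os2)
  }
  if (length(spec$omics_specs) != 2L)
    stop("pair simulations need exactly 1 or 2 omics specs")
  spec
}

#' Write a simulated cohort to delimited files
#'
#' Writes one matrix TSV and one type sidecar per source, plus the true
#' labels, into `dir`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in sim$datasets)
    write_omics(ds, file.path(dir, paste0(ds$name, ".tsv")),
                types_path = file.path(dir, paste0(ds$name, ".types.tsv")))
  write_labels(sim$true_labels, file.path(dir, "true_labels.tsv"))
  invisible(dir)
}
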