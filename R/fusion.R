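#' Vertically concatenate omics sources into one feature-by-sample matrix
#'
#' Stacks the (sample-aligned, standardized) sources feature-wise: the result
#' holds all features of all sources as rows over the shared samples as
#' columns, with the originating source recorded per feature. Feature ids
#' clashing across sources are disambiguated by prefixing the source name.
#'
#' @param datasets List of [omics_dataset()] objects with identical sample
#'   ids in identical order (see [align_samples()]).
#' @return An object of class `concat_features`: list with `matrix`
#'   (features x samples), `origin` (per-feature source label) and
#'   `var_types`.
#' @export
concatenate_omics <- function(datasets) {
  if (inherits(datasets, "omics_dataset")) datasets <- list(datasets)
  sids <- sample_ids(datasets[[1L]])
  for (ds in datasets[-1L])
    if (!identical(sample_ids(ds), sids))
      stop("datasets are not sample-aligned; run align_samples() first")
  mats <- lapply(datasets, function(ds) t(ds$values))
  origin <- rep(vapply(datasets, `[[`, "", "name"),
                vapply(mats, nrow, 0L))
  types <- unlist(lapply(datasets, function(ds) unname(ds$var_types)))
  m <- do.call(rbind, mats)
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m) %in% rownames(m)[duplicated(rownames(m))]
    rownames(m)[dup] <- paste(origin[dup], rownames(m)[dup], sep = ".")
    if (anyDuplicated(rownames(m)))
      stop("feature ids not unique even after source prefixing")
  }
  structure(list(matrix = m, origin = origin,
                 var_types = stats::setNames(types, rownames(m))),
            class = "concat_features")
}

#' Split a concatenated matrix back into its sources
#'
#' @param concat A `concat_features` object.
#' @return Named list of feature x sample matrices, one per source.
#' @export
split_by_origin <- function(concat) {
  lapply(split(seq_len(nrow(concat$matrix)), concat$origin)[unique(concat$origin)],
         function(i) concat$matrix[i, , drop = FALSE])
}

#' Correlation between two features of possibly different variable types
#'
#' Type-pair dispatch: continuous-continuous uses Pearson; any pair involving
#' an ordinal feature uses Spearman; binary-continuous is the point-biserial
#' coefficient (Pearson on the level codes) and binary-binary the phi
#' coefficient (again Pearson on the codes); any pair involving a categorical
#' feature uses Cramer's V, a sign-free association in \[0, 1\] (the partner
#' is discretized into quantile bins when it is not already discrete).
#' Only pairwise-complete observations are used; with fewer than 3 complete
#' pairs, or when either feature is constant on the complete pairs, the
#' correlation is recorded as 0 (neutral dissimilarity 0.5) with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @param type_x,type_y Variable type tags.
#' @return A correlation in \[-1, 1\].
#' @export
mixed_correlation <- function(x, y, type_x = "continuous",
                              type_y = "continuous") {
  stopifnot(length(x) == length(y),
            type_x %in% VAR_TYPES, type_y %in% VAR_TYPES)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 pairwise-complete observations; correlation set to 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant feature on complete pairs; correlation set to 0")
    return(0)
  }
  if (type_x == "categorical" || type_y == "categorical")
    return(cramers_v(bin_for_table(x, type_x), bin_for_table(y, type_y)))
  method <- if (type_x == "ordinal" || type_y == "ordinal") "spearman"
            else "pearson"
  r <- stats::cor(x, y, method = method)
  if (is.na(r)) 0 else r
}

# Discretize a feature for a contingency table: discrete types keep their
# level codes; continuous features are cut into (up to 4) quantile bins.
bin_for_table <- function(x, type) {
  if (type != "continuous" || length(unique(x)) <= 4L) return(x)
  cuts <- unique(stats::quantile(x, probs = c(0.25, 0.5, 0.75),
                                 names = FALSE))
  findInterval(x, cuts)
}

# Cramer's V from a contingency table (no continuity correction).
cramers_v <- function(x, y) {
  tab <- table(x, y)
  if (min(dim(tab)) < 2L) return(0)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1L)))
  min(v, 1)
}

#' Mixed-type correlation matrix of concatenated features
#'
#' Applies [mixed_correlation()]'s type-pair dispatch to every feature pair
#' of the concatenated matrix, using pairwise-complete observations
#' throughout, so missing cells never require imputation. Undefined entries
#' (constant features, < 3 complete pairs) are set to 0 and counted in a
#' single warning, keeping the matrix complete for the MDS step.
#'
#' @param concat A `concat_features` object (see [concatenate_omics()]).
#' @return Symmetric correlation matrix R with unit diagonal.
#' @export
feature_correlation <- function(concat) {
  m <- concat$matrix
  types <- unname(concat$var_types)
  p <- nrow(m)
  obs <- !is.na(m)
  n_pair <- tcrossprod(obs * 1)
  R <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  ord <- types == "ordinal"
  if (any(ord)) {
    Rs <- suppressWarnings(stats::cor(t(m), method = "spearman",
                                      use = "pairwise.complete.obs"))
    sel <- outer(ord, ord, "|")
    R[sel] <- Rs[sel]
  }
  cat_i <- which(types == "categorical")
  for (i in cat_i) {
    for (j in seq_len(p)) {
      if (i == j) next
      ok <- obs[i, ] & obs[j, ]
      R[i, j] <- R[j, i] <- if (sum(ok) < 3L) NA_real_ else
        cramers_v(bin_for_table(m[i, ok], types[i]),
                  bin_for_table(m[j, ok], types[j]))
    }
  }
  R[n_pair < 3L] <- NA_real_
  n_undef <- sum(is.na(R[upper.tri(R)]))
  if (n_undef)
    warning(n_undef, " feature pair(s) with undefined correlation set to 0")
  R[is.na(R)] <- 0
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- list(rownames(m), rownames(m))
  R
}

#' Feature dissimilarity D = (1 - R) / 2
#'
#' Maps correlation 1 to distance 0, correlation 0 to 0.5 and correlation -1
#' to 1, so strongly co-varying features are close and anti-correlated
#' features maximally distant. Because Cramer's V is non-negative,
#' categorical pairs live in \[0, 0.5\].
#'
#' @param R Symmetric correlation matrix with unit diagonal (entries in
#'   \[-1, 1\]).
#' @return Object of class `feature_dissimilarity`: list with `D` (symmetric,
#'   zero diagonal, entries in \[0, 1\]) and `R`.
#' @export
feature_dissimilarity <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(R)) > 1 + 1e-8) stop("correlation entries must lie in [-1, 1]")
  D <- (1 - R) / 2
  D[D < 0] <- 0; D[D > 1] <- 1
  diag(D) <- 0
  structure(list(D = D, R = R), class = "feature_dissimilarity")
}

#' Embed features in two dimensions by non-metric MDS
#'
#' Minimizes Kruskal stress-1 over monotone transforms of the feature
#' dissimilarities, starting from the classical (metric) MDS solution so the
#' result is deterministic. Coordinates are then min-max rescaled so each
#' axis spans the unit interval; the smoothing grid lives on this unit
#' square. Because the embedding is computed once on the concatenated
#' features, coordinates are comparable across omics sources.
#'
#' @param fd A `feature_dissimilarity` (or a plain symmetric dissimilarity
#'   matrix).
#' @param origin Optional per-feature source labels (taken from a
#'   `concat_features` via [embed_concat()]).
#' @param maxit,tol Iteration cap and convergence tolerance of the stress
#'   minimization.
#' @return Object of class `feature_embedding`: list with `coords` (features
#'   x 2 matrix, columns `u1`, `u2`, rows named by feature id, each axis
#'   spanning \[0, 1\]), `coords_raw` (the stress-minimizing configuration
#'   before the axis-wise rescaling, which preserves the embedded geometry
#'   exactly), `stress` (final Kruskal stress-1, as a fraction) and
#'   `origin`.
#' @export
embed_features <- function(fd, origin = NULL, maxit = 300L, tol = 1e-6) {
  D <- if (inherits(fd, "feature_dissimilarity")) fd$D else fd
  p <- nrow(D)
  if (p < 3L) stop("need at least 3 features to embed in 2 dimensions")
  # isoMDS requires positive off-diagonal dissimilarities
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    eps <- max(D) * 1e-8 + 1e-12
    D[D == 0] <- eps
    diag(D) <- 0
  }
  init <- stats::cmdscale(D, k = 2)
  if (ncol(init) < 2L || any(!is.finite(init)))
    init <- cbind(init[, 1L], stats::runif(p, -1e-6, 1e-6))
  fit <- MASS::isoMDS(stats::as.dist(D), y = init, k = 2, maxit = maxit,
                      tol = tol, trace = FALSE)
  raw <- fit$points
  coords <- raw
  for (j in 1:2) {
    rng <- range(coords[, j])
    coords[, j] <- if (diff(rng) == 0) 0.5 else
      (coords[, j] - rng[1]) / diff(rng)
  }
  dimnames(coords) <- dimnames(raw) <- list(rownames(D), c("u1", "u2"))
  structure(list(coords = coords, coords_raw = raw,
                 stress = fit$stress / 100, origin = origin),
            class = "feature_embedding")
}

#' @rdname embed_features
#' @param concat A `concat_features` object; computes the mixed-type
#'   correlation, the dissimilarity and the embedding in one call.
#' @export
embed_concat <- function(concat, maxit = 300L, tol = 1e-6) {
  fd <- feature_dissimilarity(feature_correlation(concat))
  emb <- embed_features(fd, origin = concat$origin, maxit = maxit, tol = tol)
  emb$var_types <- concat$var_types
  emb
}

#' Smooth one patient's feature intensities over the embedding
#'
#' Fits a thin-plate regression spline surface (a bivariate GAM smooth) of
#' the patient's intensities on the embedded feature coordinates, with the
#' smoothing parameter chosen by generalized cross-validation, and evaluates
#' it on the (n+1) x (n+1) unit-square lattice. Element `s * (n + 1) + t + 1`
#' of the result is the smoothed intensity at coordinate (s/n, t/n),
#' s, t = 0..n. Missing intensities are excluded from the fit.
#'
#' @param embedding A `feature_embedding`.
#' @param intensities Numeric vector of the patient's values, named by
#'   feature id or aligned with `features`.
#' @param grid_n Grid resolution n.
#' @param features Optional character vector restricting the fit to a feature
#'   subset (e.g. one omics source).
#' @param basis_k Requested basis dimension; reduced (with a warning) when
#'   fewer features than `2 * basis_k` are available.
#' @return Numeric vector of length `(grid_n + 1)^2` with attributes
#'   `grid_n` and `n_features`.
#' @export
smooth_patient <- function(embedding, intensities, grid_n = 50L,
                           features = NULL, basis_k = 60L) {
  coords <- embedding$coords
  if (!is.null(features)) {
    coords <- coords[intersect(rownames(coords), features), , drop = FALSE]
  }
  if (!is.null(names(intensities)))
    intensities <- intensities[rownames(coords)]
  if (length(intensities) != nrow(coords))
    stop("one intensity per embedded feature is required")
  ok <- !is.na(intensities)
  if (!any(ok)) stop("all intensities missing for this patient")
  y <- intensities[ok]
  uu <- coords[ok, , drop = FALSE]
  k_eff <- min(basis_k, floor(length(y) / 2))
  if (k_eff < 3L) k_eff <- 3L
  if (k_eff < basis_k && length(y) < 2L * basis_k && k_eff < 10L)
    warning("few features (", length(y), "); basis reduced to k = ", k_eff)
  if (length(y) <= k_eff + 1L)
    stop("too few non-missing features (", length(y),
         ") for a basis of dimension ", k_eff)
  df <- data.frame(y = y, u1 = uu[, 1], u2 = uu[, 2])
  fit <- mgcv::gam(y ~ s(u1, u2, bs = "tp", k = k_eff), data = df,
                   method = "GCV.Cp")
  st <- rep(0:grid_n, each = grid_n + 1L)
  tt <- rep(0:grid_n, times = grid_n + 1L)
  grid <- data.frame(u1 = st / grid_n, u2 = tt / grid_n)
  vals <- as.numeric(mgcv::predict.gam(fit, newdata = grid))
  attr(vals, "grid_n") <- grid_n
  attr(vals, "n_features") <- length(y)
  vals
}

#' Smooth all patients of one (or a merged group of) omics source(s)
#'
#' @param embedding A `feature_embedding` of the concatenated features.
#' @param concat The matching `concat_features`.
#' @param source Source label(s) whose features are smoothed; `NULL` uses
#'   all features.
#' @param grid_n Grid resolution n.
#' @param basis_k Requested basis dimension (see [smooth_patient()]).
#' @return Object of class `smoothed_profiles`: samples x (n+1)^2 matrix with
#'   attributes `grid_n` and `source`.
#' @export
smooth_profiles <- function(embedding, concat, source = NULL, grid_n = 50L,
                            basis_k = 60L) {
  m <- concat$matrix
  if (!is.null(source)) {
    keep <- concat$origin %in% source
    if (!any(keep)) stop("no features with origin in: ",
                         paste(source, collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  feats <- rownames(m)
  out <- vapply(seq_len(ncol(m)), function(j) {
    smooth_patient(embedding, stats::setNames(m[, j], feats),
                   grid_n = grid_n, features = feats, basis_k = basis_k)
  }, numeric((grid_n + 1L)^2))
  out <- t(out)
  rownames(out) <- colnames(m)
  structure(out, grid_n = grid_n,
            source = if (is.null(source)) unique(concat$origin) else source,
            class = c("smoothed_profiles", "matrix", "array"))
}

#' Reshape a smoothed profile vector into its (n+1) x (n+1) grid
#'
#' @param profile Length-(n+1)^2 vector from [smooth_patient()] (or one row
#'   of a `smoothed_profiles` matrix).
#' @param grid_n Grid resolution; taken from the attribute when present.
#' @return Matrix with rows indexed by s (u1) and columns by t (u2).
#' @export
ftp_grid <- function(profile, grid_n = attr(profile, "grid_n")) {
  if (is.null(grid_n)) grid_n <- round(sqrt(length(profile))) - 1L
  stopifnot(length(profile) == (grid_n + 1L)^2)
  matrix(profile, grid_n + 1L, grid_n + 1L, byrow = TRUE)
}

#' Render a feature topology plot
#'
#' Filled-contour rendering of a smoothed profile over the unit square with
#' the blue-yellow-red diverging palette (low, intermediate, high intensity).
#' Pass a common `zlim` to compare several profiles on one color scale.
#'
#' @param profile Profile vector (see [ftp_grid()]).
#' @param grid_n Grid resolution; taken from the attribute when present.
#' @param zlim Color scale limits; defaults to the profile range.
#' @param main Plot title.
#' @param file Optional `.png` or `.pdf` path; plots to the active device
#'   when `NULL`.
#' @return The underlying grid matrix, invisibly.
#' @export
ftp_render <- function(profile, grid_n = attr(profile, "grid_n"),
                       zlim = NULL, main = "", file = NULL) {
  g <- ftp_grid(profile, grid_n)
  n <- nrow(g) - 1L
  if (is.null(zlim)) zlim <- range(g)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#67A9CF", "#FFFFBF", "#EF8A62", "#B2182B"))
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 600, 600)
    else grDevices::pdf(file, 6, 6)
    on.exit(grDevices::dev.off())
  }
  graphics::filled.contour((0:n) / n, (0:n) / n, g, zlim = zlim,
                           color.palette = pal, main = main,
                           xlab = "u1", ylab = "u2")
  invisible(g)
}

#' Serialize profiles or an embedding to TSV
#'
#' @param profiles A `smoothed_profiles` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(sample_id = rownames(profiles),
                   unclass(profiles)[, , drop = FALSE], check.names = FALSE)
  colnames(df)[-1L] <- paste0("g", seq_len(ncol(profiles)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @param embedding A `feature_embedding`.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(feature_id = rownames(embedding$coords),
                   u1 = embedding$coords[, 1], u2 = embedding$coords[, 2])
  if (!is.null(embedding$origin)) df$origin <- embedding$origin
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
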