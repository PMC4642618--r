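#' Patient dissimilarity from smoothed profiles
#'
#' One minus the Pearson correlation between two patients' smoothed profile
#' vectors: patients whose feature topology agrees have dissimilarity near 0,
#' perfectly inverted topologies give 2. A constant profile has undefined
#' correlation; its dissimilarities are set to 1 (neutral) with a warning.
#'
#' @param profiles A `smoothed_profiles` matrix (samples x grid), or any
#'   numeric matrix with one row per patient.
#' @return Symmetric dissimilarity matrix with zero diagonal, entries in
#'   \[0, 2\].
#' @export
patient_dissimilarity <- function(profiles) {
  x <- unclass(profiles)
  C <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  if (anyNA(C)) {
    warning("constant profile(s); their dissimilarities set to 1")
    C[is.na(C)] <- 0
  }
  D <- 1 - C
  D[D < 0] <- 0; D[D > 2] <- 2
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Partitioning around medoids with multiple starts
#'
#' Runs the BUILD + SWAP k-medoids algorithm (via [cluster::pam()]) from the
#' BUILD initialization and from `nstart - 1` additional random medoid sets,
#' keeping the solution with the smallest total dissimilarity to medoids.
#' SWAP is a local search; the restarts make reaching the global optimum on
#' small instances reliable while staying deterministic given `seed`.
#' Clusters are relabeled 1..K in order of first appearance over the sample
#' order, so labels are reproducible regardless of medoid indices.
#'
#' @param d Symmetric dissimilarity matrix with sample ids as dimnames.
#' @param k Number of clusters (1 <= k <= n).
#' @param nstart Total number of starts (1 = plain BUILD + SWAP).
#' @param seed Seed for the random restarts.
#' @param source Optional label recorded in the solution.
#' @return Object of class `cluster_solution`: list with `labels` (named
#'   integer vector in 1..K), `medoid_ids`, `K`, `objective` (total
#'   dissimilarity of samples to their medoids), `gap_curve` (`NULL` here;
#'   filled by [gap_select()]) and `source`.
#' @export
pam_cluster <- function(d, k, nstart = 5L, seed = 1L, source = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  ids <- rownames(d)
  if (k == n) {               # every sample its own medoid
    return(structure(list(
      labels = stats::setNames(seq_len(n), ids),
      medoid_ids = if (is.null(ids)) seq_len(n) else ids,
      K = as.integer(k), objective = 0, gap_curve = NULL, source = source),
      class = "cluster_solution"))
  }
  inits <- list(NULL)
  if (nstart > 1L) {
    set.seed(seed)
    inits <- c(inits, lapply(seq_len(nstart - 1L),
                             function(i) sort(sample.int(n, k))))
  }
  best <- NULL
  best_obj <- Inf
  for (init in inits) {
    fit <- if (is.null(init))
      cluster::pam(stats::as.dist(d), k = k, keep.diss = FALSE)
    else
      cluster::pam(stats::as.dist(d), k = k, medoids = init,
                   keep.diss = FALSE)
    obj <- sum(d[cbind(seq_len(n), fit$id.med[fit$clustering])])
    if (obj < best_obj - 1e-12) {
      best <- fit
      best_obj <- obj
    }
  }
  raw <- best$clustering
  relab <- match(raw, unique(raw))
  med_ids <- best$id.med[unique(raw)]
  structure(list(labels = stats::setNames(as.integer(relab), ids),
                 medoid_ids = if (is.null(ids)) med_ids else ids[med_ids],
                 K = as.integer(k), objective = best_obj,
                 gap_curve = NULL, source = source),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution", if (!is.null(x$source))
    paste0("[", paste(x$source, collapse = "+"), "]"), ": K =", x$K,
    "; sizes:", paste(table(x$labels), collapse = "/"), "\n")
  if (!is.null(x$gap_curve))
    cat("  gap-selected from k = 1..", max(x$gap_curve$k), "\n", sep = "")
  invisible(x)
}

# Total within-cluster dissimilarity to medoids for rows of X under the
# 1 - Pearson metric.
row_dissimilarity <- function(X) {
  C <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  C[is.na(C)] <- 0
  D <- 1 - C
  D[D < 0] <- 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Choose the number of clusters by the gap statistic
#'
#' For each candidate k, PAM is run on the 1 - correlation dissimilarity of
#' the rows of `X` and the within-cluster dispersion W(k) (total
#' dissimilarity to medoids) is compared with its expectation under `B`
#' reference data sets drawn uniformly over the observed range of every
#' column: gap(k) = mean_b log W*(k, b) - log W(k). By default K is the
#' smallest k whose gap lies within one standard error of the first local
#' maximum of the gap curve (the `"firstSEmax"` rule of
#' [cluster::maxSE()]); `"Tibs2001SEmax"` is the original smallest-k rule
#' (smallest k with gap(k) >= gap(k+1) - se(k+1)), which can stop at k = 1
#' when the curve is flat before the true K; `"max"` takes the global
#' maximum. The scan starts at k = 1 so "no cluster structure" is
#' representable.
#'
#' @param X Numeric matrix with one row per object to cluster (patients with
#'   their profile vectors, or features with their expression vectors).
#' @param k_max Largest k scanned.
#' @param B Number of reference data sets (>= 10).
#' @param seed Seed for the reference draws and PAM restarts.
#' @param nstart PAM starts per fit.
#' @param rule `"firstSEmax"`, `"Tibs2001SEmax"` or `"max"`.
#' @param reference `"uniform"` draws each reference column uniformly over
#'   its observed range; `"pca"` draws uniformly in the principal-component
#'   rotation of the data and rotates back, which respects strong column
#'   collinearity (appropriate for smoothed profile vectors, whose grid
#'   coordinates are highly correlated).
#' @param source Optional label recorded in the solution.
#' @return A `cluster_solution` at the selected K whose `gap_curve` is a
#'   data frame with columns `k`, `logW`, `E_logW`, `gap`, `se`.
#' @export
gap_select <- function(X, k_max = 6L, B = 50L, seed = 1L, nstart = 5L,
                       rule = c("firstSEmax", "Tibs2001SEmax", "max"),
                       reference = c("uniform", "pca"), source = NULL) {
  rule <- match.arg(rule)
  reference <- match.arg(reference)
  stopifnot(k_max >= 2L, B >= 10L)
  X <- as.matrix(X)
  n <- nrow(X)
  k_max <- min(k_max, n - 1L)
  if (reference == "pca" && anyNA(X)) {
    warning("PCA-rotated reference needs complete data; using uniform")
    reference <- "uniform"
  }
  d_obs <- row_dissimilarity(X)
  W_k <- function(d, k, s) {
    sol <- pam_cluster(d, k, nstart = nstart, seed = s)
    med <- match(sol$medoid_ids, rownames(d))
    if (anyNA(med)) med <- sol$medoid_ids   # unnamed matrix
    sum(d[cbind(seq_len(nrow(d)), med[sol$labels])])
  }
  safe_log <- function(w) {
    if (any(w <= 0)) warning("zero within-cluster dispersion; log guarded")
    log(pmax(w, 1e-12))
  }
  logW <- safe_log(vapply(seq_len(k_max), function(k)
    W_k(d_obs, k, seed + k), numeric(1)))
  if (reference == "pca") {
    mu <- colMeans(X)
    V <- svd(sweep(X, 2, mu), nu = 0)$v
    rng <- apply(sweep(X, 2, mu) %*% V, 2, range)
  } else {
    rng <- apply(X, 2, range, na.rm = TRUE)
  }
  set.seed(seed)
  logW_star <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    Xb <- apply(rng, 2, function(r) stats::runif(n, r[1], r[2]))
    if (reference == "pca") Xb <- sweep(Xb %*% t(V), 2, mu, "+")
    db <- row_dissimilarity(Xb)
    logW_star[b, ] <- safe_log(vapply(seq_len(k_max), function(k)
      W_k(db, k, seed + 1000L * b + k), numeric(1)))
  }
  E_logW <- colMeans(logW_star)
  gap <- E_logW - logW
  se <- apply(logW_star, 2, stats::sd) * sqrt(1 + 1 / B)
  K <- cluster::maxSE(gap, se, method = switch(rule,
    max = "globalmax", Tibs2001SEmax = "Tibs2001SEmax",
    firstSEmax = "firstSEmax"))
  sol <- pam_cluster(d_obs, K, nstart = nstart, seed = seed, source = source)
  sol$gap_curve <- data.frame(k = seq_len(k_max), logW = logW,
                              E_logW = E_logW, gap = gap, se = se)
  sol
}

#' Average the smoothed profiles within each cluster
#'
#' The element-wise mean profile of a cluster's members is the numeric
#' content of its representative feature topology plot.
#'
#' @param profiles A `smoothed_profiles` matrix.
#' @param solution A `cluster_solution` whose labels cover the profiled
#'   samples.
#' @return Matrix with one row per cluster (rownames `"1"`.. `"K"`), same
#'   grid attributes as `profiles`.
#' @export
cluster_average_ftp <- function(profiles, solution) {
  x <- unclass(profiles)
  lab <- solution$labels[rownames(x)]
  if (anyNA(lab))
    stop("labels missing for sample(s): ",
         paste(rownames(x)[is.na(lab)], collapse = ", "))
  counts <- table(factor(lab, levels = seq_len(solution$K)))
  if (any(counts == 0))
    stop("empty cluster(s): ", paste(names(counts)[counts == 0], collapse = ", "))
  avg <- rowsum(x, lab) / as.numeric(counts)
  structure(avg, grid_n = attr(profiles, "grid_n"),
            source = attr(profiles, "source"),
            class = c("smoothed_profiles", "matrix", "array"))
}

#' Write a gap curve to TSV
#'
#' @param solution A `cluster_solution` with a `gap_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gap_curve <- function(solution, path) {
  if (is.null(solution$gap_curve)) stop("solution has no gap curve")
  utils::write.table(solution$gap_curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
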