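#' Filter non-expressed and non-informative features
#'
#' Two-stage per-source filter applied before concatenation: continuous
#' features whose mean lies strictly below the `mean_q` quantile of the
#' continuous feature means are dropped (non-expressed), then continuous
#' features whose standard deviation lies strictly below the `sd_q` quantile
#' of the remaining continuous feature SDs are dropped (non-informative).
#' Non-continuous features are exempt from both quantile stages; constant
#' features of any type are always removed. Means and SDs use non-missing
#' values only.
#'
#' @param ds An [omics_dataset()].
#' @param mean_q,sd_q Quantile cutoffs in \[0, 1).
#' @return A list with elements `dataset` (the filtered [omics_dataset()])
#'   and `report` (class `filter_report`: `kept_ids`,
#'   `dropped_low_mean_ids`, `dropped_low_sd_ids`; constant features are
#'   reported among the low-SD drops).
#' @export
filter_features <- function(ds, mean_q = 0.3, sd_q = 0.3) {
  stopifnot(mean_q >= 0, mean_q < 1, sd_q >= 0, sd_q < 1)
  v <- ds$values
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  constant <- is.na(sds) | sds == 0
  is_cont <- ds$var_types == "continuous"

  low_mean <- rep(FALSE, ncol(v))
  cand <- is_cont & !constant
  if (mean_q > 0 && any(cand)) {
    mu <- colMeans(v[, cand, drop = FALSE], na.rm = TRUE)
    low_mean[cand] <- mu < stats::quantile(mu, mean_q, names = FALSE)
  }
  low_sd <- rep(FALSE, ncol(v))
  cand2 <- cand & !low_mean
  if (sd_q > 0 && any(cand2)) {
    s2 <- sds[cand2]
    low_sd[cand2] <- s2 < stats::quantile(s2, sd_q, names = FALSE)
  }
  drop <- constant | low_mean | low_sd
  if (all(drop))
    stop("all features of '", ds$name,
         "' removed; lower mean_q/sd_q or inspect the data")
  ids <- colnames(v)
  report <- structure(list(source = ds$name,
                           kept_ids = ids[!drop],
                           dropped_low_mean_ids = ids[low_mean],
                           dropped_low_sd_ids = ids[low_sd | constant]),
                      class = "filter_report")
  ds$values <- v[, !drop, drop = FALSE]
  ds$var_types <- ds$var_types[!drop]
  list(dataset = validate_omics_dataset(ds), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report for '", x$source, "': kept ", length(x$kept_ids),
      ", dropped ", length(x$dropped_low_mean_ids), " low-mean + ",
      length(x$dropped_low_sd_ids), " low-SD/constant\n", sep = "")
  invisible(x)
}

#' Serialize a filter report to TSV
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- rbind(
    data.frame(feature_id = report$kept_ids, status = "kept"),
    data.frame(feature_id = report$dropped_low_mean_ids,
               status = "dropped_low_mean"),
    data.frame(feature_id = report$dropped_low_sd_ids,
               status = "dropped_low_sd"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize features to zero mean and unit variance
#'
#' Continuous, ordinal and binary features are centered and scaled using
#' their non-missing mean and sample (n - 1) standard deviation, so that no
#' source or feature dominates the concatenated matrix. Categorical features
#' are left as integer level codes: they are compared downstream through a
#' sign-free association measure for which scaling is meaningless. Missing
#' values stay missing. The operation is idempotent.
#'
#' @param ds An [omics_dataset()] with no constant non-categorical features
#'   (run [filter_features()] first).
#' @return The standardized [omics_dataset()].
#' @export
standardize_features <- function(ds) {
  v <- ds$values
  scale_cols <- which(ds$var_types != "categorical")
  if (length(scale_cols)) {
    mu <- colMeans(v[, scale_cols, drop = FALSE], na.rm = TRUE)
    s <- apply(v[, scale_cols, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    if (any(is.na(s) | s == 0))
      stop("constant feature(s) cannot be standardized: ",
           paste(colnames(v)[scale_cols][is.na(s) | s == 0], collapse = ", "),
           " (filter first)")
    v[, scale_cols] <- sweep(sweep(v[, scale_cols, drop = FALSE], 2, mu),
                             2, s, "/")
  }
  ds$values <- v
  validate_omics_dataset(ds)
}
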