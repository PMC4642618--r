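#' Construct an omics data set
#'
#' An `omics_dataset` holds one omics source as a samples-by-features numeric
#' matrix together with a per-feature variable-type tag. Variable types drive
#' the mixed-type correlation used downstream: `continuous`, `ordinal` and
#' `binary` features enter correlation-based dissimilarities directly, while
#' `categorical` features carry unordered integer level codes and are compared
#' through a sign-free association measure.
#'
#' @param values Numeric matrix, samples in rows and features in columns, with
#'   unique row names (sample ids) and column names (feature ids). Missing
#'   values are allowed and preserved.
#' @param var_types Character vector of per-feature tags, one of
#'   `"continuous"`, `"ordinal"`, `"binary"`, `"categorical"`. Either unnamed
#'   and in column order, or named by feature id. `NULL` means all continuous.
#' @param name Free-text label for the source (e.g. `"mRNA"`, `"clinical"`).
#' @return An object of class `omics_dataset`: a list with elements `name`,
#'   `values`, `var_types`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' ds <- omics_dataset(m, name = "toy")
#' sample_ids(ds)
#' @export
omics_dataset <- function(values, var_types = NULL, name = "omics") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample ids as row names and feature ids as column names")
  if (is.null(var_types)) {
    var_types <- rep("continuous", ncol(values))
    names(var_types) <- colnames(values)
  } else {
    if (is.null(names(var_types))) {
      if (length(var_types) != ncol(values))
        stop("'var_types' length (", length(var_types),
             ") does not match feature count (", ncol(values), ")")
      names(var_types) <- colnames(values)
    } else {
      missing_ft <- setdiff(colnames(values), names(var_types))
      if (length(missing_ft))
        stop("no variable type given for feature(s): ",
             paste(utils::head(missing_ft, 5), collapse = ", "))
      var_types <- var_types[colnames(values)]
    }
  }
  x <- structure(list(name = name, values = values,
                      var_types = unname(var_types)),
                 class = "omics_dataset")
  names(x$var_types) <- colnames(values)
  validate_omics_dataset(x)
}

VAR_TYPES <- c("continuous", "ordinal", "binary", "categorical")

#' @rdname omics_dataset
#' @param x An `omics_dataset`.
#' @export
validate_omics_dataset <- function(x) {
  v <- x$values
  dup_s <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(v)[duplicated(colnames(v))])
  if (length(dup_f))
    stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "))
  bad <- setdiff(unique(x$var_types), VAR_TYPES)
  if (length(bad))
    stop("unknown variable type tag(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(VAR_TYPES, collapse = "/"), ")")
  if (length(x$var_types) != ncol(v))
    stop("var_types length does not equal feature count")
  is_bin <- x$var_types == "binary"
  if (any(is_bin)) {
    nlev <- vapply(which(is_bin), function(j) {
      length(unique(v[, j][!is.na(v[, j])]))
    }, integer(1))
    if (any(nlev > 2))
      stop("binary feature(s) with more than 2 distinct values: ",
           paste(colnames(v)[is_bin][nlev > 2], collapse = ", "))
  }
  if (nrow(v) && ncol(v)) {
    if (any(rowSums(!is.na(v)) == 0))
      stop("sample(s) with no non-missing value: ",
           paste(rownames(v)[rowSums(!is.na(v)) == 0], collapse = ", "))
    if (any(colSums(!is.na(v)) == 0))
      stop("feature(s) with no non-missing value: ",
           paste(colnames(v)[colSums(!is.na(v)) == 0], collapse = ", "))
  }
  x
}

#' @rdname omics_dataset
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname omics_dataset
#' @export
feature_ids <- function(x) colnames(x$values)

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset '", x$name, "': ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  cat("  types:", paste(names(table(x$var_types)), table(x$var_types),
                        sep = "=", collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  missing cells:", n_na, "\n")
  invisible(x)
}

#' Read an omics matrix from a delimited file
#'
#' Reads a TSV/CSV matrix (header row of feature ids, first column of sample
#' ids) plus an optional two-column sidecar file mapping feature id to
#' variable type. Empty cells and `NA` are read as missing and preserved;
#' no imputation is performed.
#'
#' @param path Path to the matrix file. Delimiter is inferred from the
#'   extension (`.csv` is comma, anything else tab) unless `sep` is given.
#' @param types_path Optional path to a headerless two-column TSV
#'   (`feature_id<TAB>type`). Absent means all features are continuous.
#' @param name Label for the source; defaults to the file base name.
#' @param sep Field delimiter override.
#' @param map_strings If `TRUE`, non-numeric columns are converted to integer
#'   level codes (1, 2, ...) in level sort order, tagged `categorical` unless
#'   the sidecar says otherwise, and the mapping is reported via `message()`.
#'   If `FALSE` (default) a non-numeric cell in a numeric column is an error
#'   naming the offending cell.
#' @return An [omics_dataset()].
#' @export
read_omics <- function(path, types_path = NULL, name = NULL, sep = NULL,
                       map_strings = FALSE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character",
                           comment.char = "", quote = "\"")
  sids <- raw[[1L]]
  raw <- raw[, -1L, drop = FALSE]
  types <- NULL
  if (!is.null(types_path)) {
    tt <- utils::read.table(types_path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    types <- stats::setNames(tt[[2L]], tt[[1L]])
  }
  vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                 dimnames = list(sids, colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    col <- raw[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      if (map_strings) {
        lev <- sort(unique(col[!is.na(col)]))
        num <- as.numeric(factor(col, levels = lev))
        message("read_omics: feature '", colnames(raw)[j],
                "' mapped to integer codes: ",
                paste(seq_along(lev), lev, sep = "=", collapse = ", "))
        if (is.null(types[colnames(raw)[j]]) ||
            is.na(types[colnames(raw)[j]]))
          types[colnames(raw)[j]] <- "categorical"
      } else {
        stop("non-numeric value '", col[bad[1L]], "' at sample '",
             sids[bad[1L]], "', feature '", colnames(raw)[j], "'")
      }
    }
    vals[, j] <- num
  }
  if (!is.null(types)) {
    extra <- setdiff(names(types), colnames(vals))
    types <- types[setdiff(names(types), extra)]
    full <- stats::setNames(rep("continuous", ncol(vals)), colnames(vals))
    full[names(types)] <- types
    types <- full
  }
  omics_dataset(vals, var_types = types, name = name)
}

#' Write an omics matrix (and optional type sidecar) to delimited files
#'
#' Inverse of [read_omics()]: `read_omics(write_omics(ds, f), types)` returns
#' a data set identical in values, ids and types.
#'
#' @param ds An [omics_dataset()].
#' @param path Output matrix path (delimiter from extension as in
#'   [read_omics()]).
#' @param types_path Optional path for the `feature_id<TAB>type` sidecar.
#' @return `path`, invisibly.
#' @export
write_omics <- function(ds, path, types_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = sample_ids(ds), ds$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(types_path))
    utils::write.table(data.frame(feature_ids(ds), unname(ds$var_types)),
                       types_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict several omics data sets to their shared samples
#'
#' Multi-source integration requires one patient cohort measured on every
#' platform; this keeps exactly the intersection of sample ids, in a single
#' canonical (lexicographic) order, so sources can be vertically concatenated.
#'
#' @param datasets List of [omics_dataset()] objects (at least 2).
#' @return List of `omics_dataset` objects restricted to the common samples.
#' @export
align_samples <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least 2 datasets")
  common <- Reduce(intersect, lapply(datasets, sample_ids))
  if (!length(common)) stop("no samples shared by all datasets")
  common <- sort(common)
  lapply(datasets, function(ds) {
    ds$values <- ds$values[common, , drop = FALSE]
    validate_omics_dataset(ds)
  })
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels Named integer vector (names are sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                cluster = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
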