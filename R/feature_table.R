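#' Feature intensity table
#'
#' The universal currency of the pipeline: a samples-by-features matrix of
#' non-negative LC-MS peak intensities together with per-sample metadata
#' (group label, pooled-QC flag) and optional per-feature annotations
#' (m/z, retention time, putative identity).
#'
#' @param intensity numeric matrix, samples in rows, features in columns.
#'   Values must be non-negative where present; `NA` marks missing values.
#' @param group character vector of group labels, one per sample. Pooled-QC
#'   injections conventionally carry the label `"QC"`.
#' @param is_qc logical vector flagging pooled-QC injections.
#' @param sample_id,feature_id identifiers; default to the matrix dimnames or
#'   generated `S1..`/`F1..` names. Must be unique.
#' @param annotation optional data.frame of per-feature annotations with one
#'   row per feature (e.g. columns `mz`, `rt`, `putative_id`).
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensity, group,
                          is_qc = rep(FALSE, nrow(intensity)),
                          sample_id = rownames(intensity),
                          feature_id = colnames(intensity),
                          annotation = NULL) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity)) stop("intensity must be a numeric matrix")
  n <- nrow(intensity); m <- ncol(intensity)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  if (is.null(feature_id)) feature_id <- paste0("F", seq_len(m))
  sample_id <- as.character(sample_id)
  feature_id <- as.character(feature_id)
  group <- as.character(group)
  is_qc <- as.logical(is_qc)
  if (length(sample_id) != n) stop("sample_id length does not match the intensity rows")
  if (length(feature_id) != m) stop("feature_id length does not match the intensity columns")
  if (length(group) != n) stop("group length does not match the number of samples")
  if (length(is_qc) != n) stop("is_qc length does not match the number of samples")
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup)) stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  dup <- feature_id[duplicated(feature_id)]
  if (length(dup)) stop("duplicated feature_id: ", paste(unique(dup), collapse = ", "))
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (nrow(annotation) != m) stop("annotation must have one row per feature")
  }
  dimnames(intensity) <- list(sample_id, feature_id)
  structure(
    list(intensity = intensity, sample_id = sample_id, group = group,
         is_qc = is_qc, feature_id = feature_id, annotation = annotation),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", length(x$sample_id), "samples x",
      length(x$feature_id), "features\n")
  bio <- !x$is_qc
  cat("  biological samples:", sum(bio), "in groups:",
      paste(sprintf("%s (%d)", names(table(x$group[bio])), table(x$group[bio])),
            collapse = ", "), "\n")
  cat("  pooled-QC injections:", sum(x$is_qc), "\n")
  miss <- mean(is.na(x$intensity))
  cat(sprintf("  missing values: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Subset a feature table
#'
#' @param table a [feature_table()].
#' @param samples,features logical, integer or character index into samples /
#'   features; `NULL` keeps everything.
#' @return A `feature_table`.
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  si <- if (is.null(samples)) seq_along(table$sample_id) else samples
  if (is.character(si)) si <- match(si, table$sample_id)
  fi <- if (is.null(features)) seq_along(table$feature_id) else features
  if (is.character(fi)) fi <- match(fi, table$feature_id)
  feature_table(table$intensity[si, fi, drop = FALSE],
                group = table$group[si], is_qc = table$is_qc[si],
                sample_id = table$sample_id[si],
                feature_id = table$feature_id[fi],
                annotation = if (!is.null(table$annotation))
                  table$annotation[fi, , drop = FALSE])
}

#' Keep only biological (non-QC) samples
#' @param table a [feature_table()].
#' @return A `feature_table` without the pooled-QC rows.
#' @export
biological_samples <- function(table) subset_table(table, samples = !table$is_qc)

#' Read a feature table from CSV/TSV
#'
#' The samples-in-rows layout (`orientation = "samples"`) has columns
#' `sample_id`, `group`, `is_qc`, then one numeric column per feature.
#' The transposed layout (`orientation = "features"`) has a `feature_id`
#' column and one column per sample, preceded by two metadata rows whose
#' `feature_id` is `.group` and `.is_qc`.
#'
#' @param path file path.
#' @param orientation `"samples"` (default) or `"features"`.
#' @param sep field separator; `","` default, use `"\t"` for TSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, orientation = c("samples", "features"),
                               sep = ",") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (orientation == "samples") {
    need <- c("sample_id", "group", "is_qc")
    if (!all(need %in% names(df)))
      stop("expected metadata columns: ", paste(need, collapse = ", "))
    feats <- setdiff(names(df), need)
    mat <- as.matrix(df[, feats, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- feats[!vapply(df[feats], is.numeric, logical(1))]
      stop("non-numeric intensity column(s): ", paste(bad, collapse = ", "))
    }
    feature_table(mat, group = df$group, is_qc = as.logical(df$is_qc),
                  sample_id = df$sample_id, feature_id = feats)
  } else {
    if (!"feature_id" %in% names(df)) stop("expected a feature_id column")
    ids <- df$feature_id
    g_row <- which(ids == ".group"); q_row <- which(ids == ".is_qc")
    if (length(g_row) != 1 || length(q_row) != 1)
      stop("transposed layout requires .group and .is_qc metadata rows")
    samples <- setdiff(names(df), "feature_id")
    group <- unlist(df[g_row, samples], use.names = FALSE)
    is_qc <- as.logical(unlist(df[q_row, samples], use.names = FALSE))
    vals <- df[-c(g_row, q_row), , drop = FALSE]
    raw <- as.matrix(vals[, samples, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    bad <- is.na(num) & !(is.na(raw) | raw %in% c("NA", ""))
    if (any(bad)) {
      i <- which(bad, arr.ind = TRUE)[1, ]
      stop("non-numeric cell for feature ", vals$feature_id[i[1]],
           ", sample ", samples[i[2]])
    }
    mat <- t(num)
    dimnames(mat) <- list(samples, vals$feature_id)
    feature_table(mat, group = group, is_qc = is_qc,
                  sample_id = samples, feature_id = vals$feature_id)
  }
}

#' Write a feature table to CSV/TSV
#'
#' @inheritParams read_feature_table
#' @param table a [feature_table()].
#' @return The path, invisibly.
#' @export
write_feature_table <- function(table, path,
                                orientation = c("samples", "features"),
                                sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  orientation <- match.arg(orientation)
  if (orientation == "samples") {
    df <- data.frame(sample_id = table$sample_id, group = table$group,
                     is_qc = table$is_qc, check.names = FALSE)
    df <- cbind(df, as.data.frame(table$intensity, check.names = FALSE))
  } else {
    meta <- rbind(table$group, as.character(table$is_qc))
    vals <- t(table$intensity)
    df <- data.frame(feature_id = c(".group", ".is_qc", table$feature_id),
                     rbind(meta, vals), check.names = FALSE)
    names(df)[-1] <- table$sample_id
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
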