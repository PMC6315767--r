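#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation, the precision
#' metric computed across repeated pooled-QC injections of the same material.
#'
#' @param values numeric vector (missing values are dropped).
#' @return RSD in percent.
#' @export
compute_rsd <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("RSD needs at least 2 non-missing values")
  mu <- mean(v)
  if (mu <= 0) stop("RSD is undefined for non-positive mean")
  100 * stats::sd(v) / mu
}

# per-feature RSD over the QC rows; NA where undefined
qc_rsd <- function(table) {
  qcm <- table$intensity[table$is_qc, , drop = FALSE]
  apply(qcm, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) <= 0) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  })
}

filter_report <- function(feature_id, metric_name, metric, passed, reason) {
  rep <- data.frame(feature_id = feature_id, metric, passed = passed,
                    reason = reason, stringsAsFactors = FALSE)
  names(rep)[2] <- metric_name
  class(rep) <- c("filter_report", "data.frame")
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", sum(x$passed), "of", nrow(x), "features retained (",
      sum(!x$passed), "removed)\n")
  invisible(x)
}

#' Filter features by pooled-QC RSD
#'
#' Features whose RSD across the pooled-QC injections is strictly greater
#' than `threshold` percent are removed; features whose QC RSD cannot be
#' computed (fewer than two non-missing QC values, or non-positive mean) are
#' also removed, since their technical precision cannot be certified.
#'
#' @param table a [feature_table()] with at least two QC-flagged samples.
#' @param threshold percent RSD cutoff (default 30).
#' @return A list with `table` (filtered) and `report` (per-feature RSD,
#'   pass flag, failure reason).
#' @export
filter_by_rsd <- function(table, threshold = 30) {
  stopifnot(inherits(table, "feature_table"))
  if (sum(table$is_qc) < 2)
    stop("RSD filtering needs at least 2 pooled-QC samples")
  rsd <- qc_rsd(table)
  undef <- is.na(rsd)
  fail <- undef | rsd > threshold
  reason <- rep(NA_character_, length(rsd))
  reason[undef] <- "undefined_qc_rsd"
  reason[!undef & rsd > threshold] <-
    sprintf("qc_rsd_above_%g_percent", threshold)
  list(table = subset_table(table, features = !fail),
       report = filter_report(table$feature_id, "rsd_percent", rsd,
                              !fail, reason))
}

#' Filter features by missingness in the biological samples
#'
#' Features whose fraction of missing values among the biological (non-QC)
#' samples strictly exceeds `max_fraction` are removed. A feature missing in
#' exactly `max_fraction` of the samples is retained.
#'
#' @param table a [feature_table()].
#' @param max_fraction maximum tolerated missing fraction (default 0.20).
#' @return A list with `table` and `report` (per-feature missing fraction).
#' @export
filter_by_missingness <- function(table, max_fraction = 0.20) {
  stopifnot(inherits(table, "feature_table"))
  bio <- table$intensity[!table$is_qc, , drop = FALSE]
  if (nrow(bio) < 1) stop("the table has no biological samples")
  frac <- colMeans(is.na(bio))
  fail <- frac > max_fraction
  reason <- rep(NA_character_, length(frac))
  reason[fail] <- sprintf("missing_above_%g", max_fraction)
  list(table = subset_table(table, features = !fail),
       report = filter_report(table$feature_id, "missing_fraction", frac,
                              !fail, reason))
}

#' Replace zero intensities by missing values
#'
#' LC-MS zeros are non-detections, not true zeros; they must be converted to
#' missing before the log2 transform. Emits a warning stating how many cells
#' were converted.
#'
#' @param table a [feature_table()].
#' @return The table with zeros set to `NA`.
#' @export
zeros_to_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  z <- which(table$intensity == 0)
  if (length(z)) {
    warning(length(z), " zero intensit",
            if (length(z) == 1) "y" else "ies", " converted to missing")
    table$intensity[z] <- NA_real_
  }
  table
}

#' Log2-transform a feature table
#'
#' Elementwise log2; missing values stay missing. Zero or negative
#' intensities are an error naming the offending cell — zeros must be
#' converted to missing upstream (see [zeros_to_missing()]).
#'
#' @param table a [feature_table()].
#' @return The transformed `feature_table`.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  bad <- which(table$intensity <= 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(table$intensity))
    stop("non-positive intensity at sample ", table$sample_id[ij[1]],
         ", feature ", table$feature_id[ij[2]],
         "; convert zeros to missing before log2")
  }
  table$intensity <- log2(table$intensity)
  table
}

#' Pareto scaling
#'
#' Mean-centers each feature and divides it by the square root of its sample
#' standard deviation — intermediate between no scaling and unit-variance
#' scaling, so that a scaled feature's variance equals its original standard
#' deviation. Centers and scale factors are stored for inverse transforms and
#' for projecting new samples.
#'
#' @param x numeric matrix (samples x features), or a [feature_table()]
#'   whose intensity matrix is used.
#' @return An object of class `scaled_matrix`: list with `values`, `center`,
#'   `scale` (the per-feature `sqrt(sd)`), and provenance flags.
#' @export
pareto_scale <- function(x) {
  if (inherits(x, "feature_table")) x <- x$intensity
  x <- as.matrix(x)
  nobs <- colSums(!is.na(x))
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  bad <- nobs < 2 | is.na(sds) | sds == 0
  if (any(bad)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(x)))
    stop("features with fewer than 2 values or zero standard deviation ",
         "cannot be Pareto scaled; drop: ", paste(nm[bad], collapse = ", "))
  }
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- sqrt(sds)
  vals <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  structure(list(values = vals, center = ctr, scale = scl,
                 log2_applied = NA, pareto = TRUE),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat("Pareto-scaled matrix:", nrow(x$values), "samples x",
      ncol(x$values), "features\n")
  invisible(x)
}

#' Half-minimum imputation
#'
#' Replaces each feature's missing values by half its smallest observed
#' value — the conventional below-LOD stand-in used before multivariate
#' modelling, once heavy-missingness features have been filtered out.
#'
#' @param x numeric matrix or [feature_table()].
#' @return Same type as the input, with no missing values.
#' @export
impute_half_min <- function(x) {
  tab <- NULL
  if (inherits(x, "feature_table")) { tab <- x; x <- x$intensity }
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (!any(na)) next
    if (all(na)) stop("feature ", colnames(x)[j] %||% j, " is entirely missing")
    x[na, j] <- min(x[!na, j]) / 2
  }
  if (!is.null(tab)) { tab$intensity <- x; tab } else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pre-processing chain
#'
#' Fixed order: pooled-QC RSD filter, biological-missingness filter, zeros to
#' missing, log2 transform, Pareto scaling of the biological samples.
#'
#' @param table a [feature_table()] including QC rows.
#' @param rsd_threshold percent QC-RSD cutoff (default 30).
#' @param max_missing maximum missing fraction in biological samples
#'   (default 0.20).
#' @return A list: `filtered` (raw-scale filtered table, QC rows retained),
#'   `log2` (log2 table, biological samples only), `scaled`
#'   (a `scaled_matrix` of the biological samples), `rsd_report`,
#'   `missing_report`.
#' @export
preprocess <- function(table, rsd_threshold = 30, max_missing = 0.20) {
  s1 <- filter_by_rsd(table, rsd_threshold)
  s2 <- filter_by_missingness(s1$table, max_missing)
  filtered <- suppressWarnings(zeros_to_missing(s2$table))
  lg <- log2_transform(biological_samples(filtered))
  scaled <- pareto_scale(impute_half_min(lg))
  scaled$log2_applied <- TRUE
  list(filtered = filtered, log2 = lg, scaled = scaled,
       rsd_report = s1$report, missing_report = s2$report)
}
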