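#' Principal components analysis for QC assessment
#'
#' Thin wrapper around [stats::prcomp()] returning scores, loadings and
#' explained-variation fractions — used to check that pooled-QC injections
#' cluster tightly relative to the biological samples before any supervised
#' modelling.
#'
#' @param x numeric matrix (samples x features), no missing values.
#' @param n_components number of components to keep; must not exceed the
#'   matrix rank.
#' @param center,scale. passed to [stats::prcomp()].
#' @return Object of class `pca_model`: `scores`, `loadings`, `explained`
#'   (fraction of total variance per kept component) and `cumulative`.
#' @export
fit_pca <- function(x, n_components = 2, center = TRUE, scale. = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("PCA input contains missing values; impute first")
  pr <- stats::prcomp(x, center = center, scale. = scale.)
  ev <- pr$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds the matrix rank (",
         rank, ")")
  keep <- seq_len(n_components)
  explained <- ev[keep] / sum(ev)
  structure(list(scores = pr$x[, keep, drop = FALSE],
                 loadings = pr$rotation[, keep, drop = FALSE],
                 explained = explained, cumulative = cumsum(explained),
                 rank = rank, center = pr$center, scale = pr$scale),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA:", ncol(x$scores), "components,",
      sprintf("%.1f%%", 100 * x$cumulative[length(x$cumulative)]),
      "of variance explained\n")
  invisible(x)
}
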