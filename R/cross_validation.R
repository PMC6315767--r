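#' Cross-validated OPLS-DA fit quality (R2Y and Q2)
#'
#' Fits the full model, then re-fits the complete OPLS-DA decomposition
#' (including re-centering and orthogonal-component extraction) on each
#' training partition of a deterministic round-robin K-fold split in sample
#' order, accumulating the squared prediction error of the held-out samples
#' into PRESS. `Q2 = 1 - PRESS / SS_total` with `SS_total` the total sum of
#' squares of the centered class dummy; `R2Y = 1 - SS_res / SS_total` on the
#' full fit. Per-fold regression coefficient vectors are retained — they are
#' the jack-knife replicates used by [jackknife_ci()].
#'
#' @param x numeric matrix (samples x features, no missing values) or a
#'   `scaled_matrix`.
#' @param y two-class label vector.
#' @param n_ortho orthogonal components (default 1).
#' @param n_folds number of folds, between 2 and `nrow(x)` (default 7).
#' @param center center columns within each fit (default `TRUE`).
#'
#' @return Object of class `oplsda_cv`: `R2Y`, `Q2`, `R2X_cum`, `PRESS`,
#'   `SS_total`, `n_folds`, `fold_id`, `fold_coefficients` (K x m),
#'   `full_coefficients`, `n_components` and the full `model`.
#' @export
cross_validate <- function(x, y, n_ortho = 1, n_folds = 7, center = TRUE) {
  if (inherits(x, "scaled_matrix")) { x <- x$values; center <- FALSE }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_folds < 2 || n_folds > n)
    stop("n_folds must be between 2 and the number of samples")
  full <- oplsda(x, y, n_ortho = n_ortho, center = center)
  d0 <- full$dummy
  ss_tot <- sum((d0 - mean(d0))^2)
  fold_id <- rep_len(seq_len(n_folds), n)  # round-robin in sample order
  press <- 0
  fold_coefs <- matrix(NA_real_, n_folds, ncol(x),
                       dimnames = list(NULL, full$feature_id))
  for (k in seq_len(n_folds)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2)
      stop("cross-validation fold ", k,
           " leaves a single-class training set; use fewer folds")
    fit_k <- oplsda(x[tr, , drop = FALSE], y[tr],
                    n_ortho = n_ortho, center = center)
    pred <- predict(fit_k, x[!tr, , drop = FALSE], type = "response")
    press <- press + sum((d0[!tr] - pred)^2)
    fold_coefs[k, ] <- coef(fit_k)
  }
  structure(list(
    R2Y = full$r2y, Q2 = 1 - press / ss_tot, R2X_cum = full$r2x_cum,
    PRESS = press, SS_total = ss_tot, n = n, n_folds = n_folds,
    n_components = 1L + full$n_ortho, fold_id = fold_id,
    fold_coefficients = fold_coefs,
    full_coefficients = coef(full), model = full
  ), class = "oplsda_cv")
}

#' @export
print.oplsda_cv <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA cross-validation (%d-fold): R2X(cum) = %.3f  R2Y = %.3f  Q2 = %.3f\n",
    x$n_folds, x$R2X_cum, x$R2Y, x$Q2))
  invisible(x)
}
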