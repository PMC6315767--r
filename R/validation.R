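#' Label-permutation test of an OPLS-DA model
#'
#' The class labels are shuffled `n_perm` times; the full model (including
#' cross-validated Q2) is re-fitted for each shuffle and the permuted (R2,
#' Q2) pairs are recorded together with the absolute correlation between the
#' permuted and original class dummies. Two validity criteria are evaluated:
#' the intercept at correlation zero of the least-squares line through the
#' permuted Q2 values plus the original point (correlation 1) must be <= 0
#' ("the Q2 regression line crosses zero"), or no permuted Q2 may reach the
#' original Q2 (a tie counts against the model).
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the shuffles; the report is reproducible
#'   given the seed.
#'
#' @return Object of class `oplsda_permutation`: original `R2`/`Q2`,
#'   `permuted_r2`, `permuted_q2`, `correlation`, regression intercepts
#'   `r2_intercept`/`q2_intercept`, criterion flags and `pass`.
#' @export
permutation_test <- function(x, y, n_ortho = 1, n_perm = 999, n_folds = 7,
                             seed = NULL, center = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  orig <- cross_validate(x, y, n_ortho = n_ortho, n_folds = n_folds,
                         center = center)
  d <- orig$model$dummy
  d <- d - mean(d)
  r2s <- q2s <- cors <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    dp <- ifelse(factor(yp, levels = orig$model$class_levels) ==
                   orig$model$class_levels[2], 1, -1)
    cors[i] <- abs(stats::cor(dp - mean(dp), d))
    cvp <- cross_validate(x, yp, n_ortho = n_ortho, n_folds = n_folds,
                          center = center)
    r2s[i] <- cvp$R2Y
    q2s[i] <- cvp$Q2
  }
  xs <- c(cors, 1)
  q2_int <- unname(stats::coef(stats::lm.fit(cbind(1, xs), c(q2s, orig$Q2)))[1])
  r2_int <- unname(stats::coef(stats::lm.fit(cbind(1, xs), c(r2s, orig$R2Y)))[1])
  crosses <- q2_int <= 0
  none_exceed <- all(q2s < orig$Q2)
  structure(list(
    n_permutations = n_perm, R2 = orig$R2Y, Q2 = orig$Q2,
    permuted_r2 = r2s, permuted_q2 = q2s, correlation = cors,
    r2_intercept = r2_int, q2_intercept = q2_int,
    q2_line_crosses_zero = crosses,
    no_perm_q2_exceeds_original = none_exceed,
    pass = crosses || none_exceed, seed = seed
  ), class = "oplsda_permutation")
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations): %s\n", x$n_permutations,
              if (x$pass) "pass" else "FAIL"))
  cat(sprintf("  original R2 = %.3f, Q2 = %.3f\n", x$R2, x$Q2))
  cat(sprintf("  Q2 intercept at correlation 0: %.3f (crosses zero: %s)\n",
              x$q2_intercept, x$q2_line_crosses_zero))
  cat(sprintf("  permuted Q2 below original: %s (max permuted Q2 = %.3f)\n",
              x$no_perm_q2_exceeds_original, max(x$permuted_q2)))
  invisible(x)
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F-test comparing the variation explained by the cross-validated model
#' against its predictive residual:
#' `F = ((SS_total - PRESS)/df1) / (PRESS/df2)` with `df1` the number of
#' fitted components (predictive + orthogonal) and `df2 = n - df1 - 1`; the
#' p-value is the upper tail of `F(df1, df2)`. A negative numerator (PRESS
#' above the total sum of squares) clamps to `F = 0`, `p = 1`.
#'
#' @param fit an [cross_validate()] result, or any list with elements
#'   `PRESS`, `SS_total` and `n`.
#' @param model_dof model degrees of freedom; defaults to the fitted
#'   component count when `fit` is an `oplsda_cv`.
#' @return Object of class `cv_anova`: `F`, `df1`, `df2`, `p`.
#' @export
cv_anova <- function(fit, model_dof = NULL) {
  if (is.null(model_dof)) {
    if (!is.null(fit$n_components)) model_dof <- fit$n_components
    else stop("model_dof must be given when fit carries no component count")
  }
  press <- fit$PRESS; ss_tot <- fit$SS_total; n <- fit$n
  if (is.null(press) || is.null(ss_tot) || is.null(n))
    stop("fit must provide PRESS, SS_total and n")
  if (ss_tot <= 0) stop("SS_total must be > 0")
  if (press < 0) stop("PRESS must be >= 0")
  df1 <- model_dof
  df2 <- n - model_dof - 1
  if (df2 <= 0) stop("df2 = n - model_dof - 1 must be > 0")
  f <- ((ss_tot - press) / df1) / (press / df2)
  if (!is.finite(f)) f <- Inf
  if (f < 0) f <- 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(F = f, df1 = df1, df2 = df2, p = p), class = "cv_anova")
}

#' @export
print.cv_anova <- function(x, ...) {
  cat(sprintf("CV-ANOVA: F(%g, %g) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Model verdict: validity and significance
#'
#' Combines the three validation results the pipeline computes per model
#' pair: a model is *valid* when the permutation test passes and the
#' overfitting gap `R2 - Q2` does not exceed `max_overfit` (default 0.3),
#' and *significant* when it is valid and the CV-ANOVA p-value is below
#' `alpha` (default 0.05). Vectorized, so a whole table of model summaries
#' can be assessed at once.
#'
#' @param r2,q2 goodness of fit and cross-validated goodness of prediction.
#' @param permutation_pass logical permutation-test outcome.
#' @param p_cv_anova CV-ANOVA p-value.
#' @param r2x_cum optional cumulative explained X-variation, carried through
#'   for reporting.
#' @param max_overfit maximum tolerated `R2 - Q2` (default 0.3).
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `model_verdict` with columns `r2x_cum`, `r2`,
#'   `q2`, `permutation_pass`, `r2_minus_q2`, `valid`, `p_cv_anova`,
#'   `significant`.
#' @export
model_verdict <- function(r2, q2, permutation_pass, p_cv_anova,
                          r2x_cum = NA_real_, max_overfit = 0.3,
                          alpha = 0.05) {
  gap <- r2 - q2
  valid <- permutation_pass & (gap <= max_overfit)
  out <- data.frame(r2x_cum = r2x_cum, r2 = r2, q2 = q2,
                    permutation_pass = permutation_pass,
                    r2_minus_q2 = gap, valid = valid,
                    p_cv_anova = p_cv_anova,
                    significant = valid & (p_cv_anova < alpha),
                    stringsAsFactors = FALSE)
  class(out) <- c("model_verdict", "data.frame")
  out
}

#' Assemble a verdict from fitted validation objects
#'
#' @param fit an [cross_validate()] result.
#' @param perm an [permutation_test()] result.
#' @param anova an [cv_anova()] result.
#' @param ... passed to [model_verdict()] (e.g. `max_overfit`, `alpha`).
#' @return A one-row [model_verdict()] data.frame.
#' @export
assess_model <- function(fit, perm, anova, ...) {
  model_verdict(r2 = fit$R2Y, q2 = fit$Q2,
                permutation_pass = perm$pass, p_cv_anova = anova$p,
                r2x_cum = fit$R2X_cum, ...)
}
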