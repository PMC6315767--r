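#' Two-sample t-test p-value for one feature
#'
#' Two-sided test on (already log2-transformed) values; missing values are
#' excluded. Pooled-variance (Student) by default, Welch optionally. The
#' degenerate case — zero variance in both groups — returns `p = 1` for
#' equal means and `p = 0` otherwise.
#'
#' @param group_a,group_b numeric vectors with at least 2 non-missing values
#'   each.
#' @param var_equal pooled variance (`TRUE`, default) or Welch.
#' @return The two-sided p-value.
#' @export
ttest_feature <- function(group_a, group_b, var_equal = TRUE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-missing values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Jack-knife confidence intervals from cross-validation sub-models
#'
#' The K coefficient vectors fitted on the cross-validation training folds
#' are the jack-knife replicates. The standard error per feature is
#' `sqrt((K-1)/K * sum((b_k - mean(b))^2))` and the interval is the
#' full-model coefficient plus/minus `t(1-(1-level)/2, K-1)` standard
#' errors. Features whose interval covers zero have unreliable model
#' coefficients and are dropped by the cascade.
#'
#' @param coefficients K x m matrix of per-fold feature coefficients, or an
#'   `oplsda_cv` object (its fold coefficients are used).
#' @param center full-model coefficient vector the interval is centered on;
#'   defaults to the `oplsda_cv` full-model coefficients or the fold means.
#' @param level confidence level (default 0.95).
#' @return data.frame with `estimate`, `se`, `ci_low`, `ci_high`,
#'   `spans_zero`.
#' @export
jackknife_ci <- function(coefficients, center = NULL, level = 0.95) {
  if (inherits(coefficients, "oplsda_cv")) {
    if (is.null(center)) center <- coefficients$full_coefficients
    coefficients <- coefficients$fold_coefficients
  }
  coefficients <- as.matrix(coefficients)
  k <- nrow(coefficients)
  if (k < 2) stop("jack-knife needs at least 2 cross-validation sub-models")
  if (is.null(center)) center <- colMeans(coefficients)
  dev <- sweep(coefficients, 2, colMeans(coefficients), "-")
  se <- sqrt((k - 1) / k * colSums(dev^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  lo <- center - tq * se
  hi <- center + tq * se
  data.frame(feature_id = colnames(coefficients) %||%
               as.character(seq_len(ncol(coefficients))),
             estimate = unname(center), se = unname(se),
             ci_low = unname(lo), ci_high = unname(hi),
             spans_zero = unname(lo <= 0 & hi >= 0),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, order-preserving.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' ROC AUC of a single feature, with classifier-quality band
#'
#' The area under the ROC curve equals the rank-sum (Mann-Whitney)
#' probability `P(A > B) + P(A = B)/2`; it is folded to `>= 0.5` so the
#' marker quality is direction-agnostic. Bands: 0.9-1.0 excellent, 0.8-0.9
#' good, 0.7-0.8 fair, 0.6-0.7 poor, 0.5-0.6 failed; values below
#' `exclude_below` (default 0.7) carry an exclusion flag.
#'
#' @param group_a,group_b numeric vectors, at least 1 non-missing value each.
#' @param exclude_below AUC below which the feature is flagged for exclusion.
#' @return list with `auc`, `band`, `excluded`.
#' @export
roc_auc <- function(group_a, group_b, exclude_below = 0.7) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b)) stop("both groups need non-missing values")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  auc <- u / (length(a) * length(b))
  auc <- max(auc, 1 - auc)
  band <- if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good"
  else if (auc >= 0.7) "fair"
  else if (auc >= 0.6) "poor"
  else "failed"
  list(auc = auc, band = band, excluded = auc < exclude_below)
}

#' Q-Q straightness check of normality
#'
#' R-squared of the least-squares line through the ordered sample values
#' against standard normal quantiles at plotting positions `(i - 0.5)/n`.
#' High straightness (R2 at or above the threshold) is taken as consistent
#' with normality; bimodal or heavily censored markers fall well below it.
#'
#' @param values numeric vector, at least 3 non-missing values, not constant.
#' @param r2_min threshold for the `is_normal` flag (default 0.95).
#' @return list with `r2` and `is_normal`.
#' @export
qq_normality <- function(values, r2_min = 0.95) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n < 3) stop("Q-Q check needs at least 3 non-missing values")
  if (stats::sd(v) == 0) stop("Q-Q check is undefined for constant values")
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  r2 <- stats::cor(v, q)^2
  list(r2 = r2, is_normal = r2 >= r2_min)
}

#' Group fold change on the raw intensity scale
#'
#' @param group_a,group_b raw-scale values; both group means must be > 0.
#' @return list with `ratio` (= mean(A)/mean(B)) and `log2_ratio`.
#' @export
fold_change <- function(group_a, group_b) {
  ma <- mean(group_a, na.rm = TRUE); mb <- mean(group_b, na.rm = TRUE)
  if (!is.finite(ma) || !is.finite(mb) || ma <= 0 || mb <= 0)
    stop("fold change needs positive group means")
  ratio <- ma / mb
  list(ratio = ratio, log2_ratio = log2(ratio))
}

#' Correlate a marker with a per-sample covariate
#'
#' @param marker_values,covariate paired per-sample values (>= 3 complete
#'   pairs, neither constant).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` and two-sided `p`.
#' @export
correlate_with_covariate <- function(marker_values, covariate,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(marker_values) & !is.na(covariate)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing observations")
  x <- marker_values[ok]; y <- covariate[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for constant input")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Marker-cascade thresholds
#'
#' @param alpha_t t-test p-value cutoff (keep `p <= alpha_t`).
#' @param alpha_q BH q-value cutoff (keep `q <= alpha_q`).
#' @param auc_min minimum ROC AUC (keep `auc >= auc_min`).
#' @param vip_total_min keep `vip_total > vip_total_min`.
#' @param require_pred_ge_ortho if `TRUE`, a feature with
#'   `vip_ortho > vip_pred` is dropped; by default it is only flagged
#'   `not_biomarker_relevant`.
#' @param qq_r2_min Q-Q straightness threshold for the `is_normal` flag.
#' @param enforce_qq if `TRUE`, non-normal survivors are dropped; by default
#'   normality is recorded but not enforced.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(alpha_t = 0.05, alpha_q = 0.05, auc_min = 0.7,
                           vip_total_min = 1.0, require_pred_ge_ortho = FALSE,
                           qq_r2_min = 0.95, enforce_qq = FALSE,
                           var_equal = TRUE) {
  for (v in c(alpha_t, alpha_q, auc_min, qq_r2_min))
    if (!is.finite(v) || v <= 0 || v > 1)
      stop("cascade thresholds must lie in (0, 1]")
  if (vip_total_min < 0) stop("vip_total_min must be >= 0")
  structure(list(alpha_t = alpha_t, alpha_q = alpha_q, auc_min = auc_min,
                 vip_total_min = vip_total_min,
                 require_pred_ge_ortho = require_pred_ge_ortho,
                 qq_r2_min = qq_r2_min, enforce_qq = enforce_qq,
                 var_equal = var_equal),
            class = "cascade_config")
}

#' Marker filtration cascade
#'
#' Applies the multi-stage filter in fixed order: per-feature t-test on log2
#' values (keep `p <= alpha_t`), jack-knife confidence interval (drop
#' intervals covering zero), Benjamini-Hochberg FDR computed across all
#' features entering the cascade (keep `q <= alpha_q`), ROC AUC (keep
#' `>= auc_min`), VIP (keep `vip_total > vip_total_min`, and flag features
#' whose orthogonal importance exceeds the predictive one as not
#' biomarker-relevant), then a Q-Q normality check on the survivors.
#' Surviving markers are ranked by total VIP, descending. Every feature's
#' record is returned, with the first stage at which it failed.
#'
#' @param table filtered raw-scale [feature_table()] containing the two
#'   groups being compared (QC rows are ignored). Zeros are treated as
#'   missing.
#' @param model the fitted [oplsda()] model for the same features.
#' @param cv the [cross_validate()] result supplying the jack-knife fold
#'   coefficients.
#' @param groups length-2 character vector `c(case, reference)`; fold
#'   changes are case/reference.
#' @param config a [cascade_config()].
#' @return data.frame of class `marker_records`: per-feature evidence
#'   (`p_value`, `q_value`, `auc`, `auc_band`, `ci_low`, `ci_high`,
#'   `spans_zero`, `vip_pred`, `vip_ortho`, `vip_total`, `vip_ratio`,
#'   `ratio`, `log2_ratio`, `qq_r2`, `is_normal`,
#'   `not_biomarker_relevant`), the `drop_stage` (`NA` for selected
#'   markers), `selected` and `final_rank`.
#' @export
select_markers <- function(table, model, cv, groups,
                           config = cascade_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "oplsda"),
            inherits(cv, "oplsda_cv"), length(groups) == 2)
  if (!all(groups %in% table$group))
    stop("groups not present in the table: ",
         paste(setdiff(groups, table$group), collapse = ", "))
  if (!identical(table$feature_id, model$feature_id))
    stop("the table and the model cover different features")
  m <- length(table$feature_id)
  bio <- biological_samples(table)
  ia <- bio$group == groups[1]; ib <- bio$group == groups[2]
  raw <- bio$intensity
  raw[raw == 0] <- NA_real_

  vips <- vip(model)
  jk <- jackknife_ci(cv)

  p <- auc <- ratio <- l2r <- qq_r2 <- rep(NA_real_, m)
  band <- rep(NA_character_, m)
  is_norm <- rep(NA, m)
  for (j in seq_len(m)) {
    a <- raw[ia, j]; b <- raw[ib, j]
    la <- log2(a); lb <- log2(b)
    p[j] <- ttest_feature(la, lb, var_equal = config$var_equal)
    rc <- roc_auc(a, b, exclude_below = config$auc_min)
    auc[j] <- rc$auc; band[j] <- rc$band
    fc <- fold_change(a, b)
    ratio[j] <- fc$ratio; l2r[j] <- fc$log2_ratio
    qq <- qq_normality(c(la, lb)[!is.na(c(la, lb))], r2_min = config$qq_r2_min)
    qq_r2[j] <- qq$r2; is_norm[j] <- qq$is_normal
  }
  q <- bh_fdr(p)

  not_relevant <- vips$vip_ortho > vips$vip_pred
  drop_stage <- rep(NA_character_, m)
  fail <- function(cond, stage) {
    hit <- is.na(drop_stage) & cond
    drop_stage[hit] <<- stage
  }
  fail(p > config$alpha_t, "t_test")
  fail(jk$spans_zero, "jackknife_ci")
  fail(q > config$alpha_q, "q_value")
  fail(auc < config$auc_min, "auc")
  fail(vips$vip_total <= config$vip_total_min, "vip_total")
  if (config$require_pred_ge_ortho) fail(not_relevant, "vip_ortho_gt_pred")
  if (config$enforce_qq) fail(!is_norm, "qq_normality")

  selected <- is.na(drop_stage)
  final_rank <- rep(NA_integer_, m)
  final_rank[selected] <- rank(-vips$vip_total[selected],
                               ties.method = "first")
  out <- data.frame(
    feature_id = table$feature_id, p_value = p, q_value = q,
    auc = auc, auc_band = band,
    ci_low = jk$ci_low, ci_high = jk$ci_high, spans_zero = jk$spans_zero,
    vip_pred = vips$vip_pred, vip_ortho = vips$vip_ortho,
    vip_total = vips$vip_total, vip_ratio = vips$vip_ratio,
    ratio = ratio, log2_ratio = l2r,
    qq_r2 = qq_r2, is_normal = is_norm,
    not_biomarker_relevant = not_relevant,
    drop_stage = drop_stage, selected = selected, final_rank = final_rank,
    stringsAsFactors = FALSE
  )
  attr(out, "groups") <- groups
  class(out) <- c("marker_records", "data.frame")
  out
}

#' @export
print.marker_records <- function(x, ...) {
  g <- attr(x, "groups")
  cat("Marker cascade", if (!is.null(g)) paste0("(", g[1], "/", g[2], ")"),
      ":", sum(x$selected), "of", nrow(x), "features selected\n")
  if (any(x$selected)) {
    sel <- as.data.frame(x)[x$selected,
                            c("feature_id", "ratio", "p_value", "q_value",
                              "auc", "vip_total", "vip_ratio", "final_rank")]
    print(sel[order(sel$final_rank), ], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
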