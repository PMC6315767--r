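#' Fit an external calibration curve
#'
#' Ordinary least-squares line `response = slope * concentration +
#' intercept` through the calibration standards. The valid concentration
#' range is the span of the standards; inverse predictions outside it are
#' flagged by [quantify_sample()].
#'
#' @param concentrations standard concentrations (ug/mL), at least 2
#'   distinct levels.
#' @param responses instrument responses (peak areas).
#' @param analyte optional analyte name.
#' @return Object of class `calibration_curve`: `slope`, `intercept`, `r2`,
#'   `range`, `degenerate` flag (all responses equal; r2 undefined).
#' @export
fit_calibration <- function(concentrations, responses, analyte = NA_character_) {
  ok <- !is.na(concentrations) & !is.na(responses)
  conc <- concentrations[ok]; resp <- responses[ok]
  if (length(unique(conc)) < 2)
    stop("calibration needs at least 2 distinct concentration levels")
  fit <- stats::lm(resp ~ conc)
  degenerate <- stats::var(resp) == 0
  r2 <- if (degenerate) NA_real_ else
    1 - sum(stats::residuals(fit)^2) / sum((resp - mean(resp))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = r2,
    range = range(conc), n = length(conc),
    degenerate = degenerate, analyte = analyte
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve", if (!is.na(x$analyte)) paste0("(", x$analyte, ")"),
      sprintf(": response = %.4g x conc %+.4g", x$slope, x$intercept), "\n")
  cat(sprintf("  r2 = %s, valid range %.3g-%.3g ug/mL (%d standards)%s\n",
              if (is.na(x$r2)) "undefined" else sprintf("%.4f", x$r2),
              x$range[1], x$range[2], x$n,
              if (x$degenerate) " [degenerate: flat responses]" else ""))
  invisible(x)
}

#' Inverse-predict a sample concentration from a calibration curve
#'
#' Converts an instrument response to ug per g of dry faeces:
#' `conc_ug_per_ml = (response - intercept) / slope`, then
#' `ug/g = conc * extract_volume_ml * dilution_factor / dry_mass_g`.
#' Predicted concentrations outside the calibration range (including
#' negative ones) are flagged, never silently clipped.
#'
#' @param curve a [fit_calibration()] result.
#' @param response instrument response.
#' @param dry_mass_g dry sample mass in grams (> 0).
#' @param extract_volume_ml extract volume in mL.
#' @param dilution_factor dilution applied before injection.
#' @param sample_id optional identifier.
#' @return data.frame (one row) with `sample_id`, `analyte`, `response`,
#'   `conc_ug_per_ml`, `ug_per_g`, `below_range`, `above_range`.
#' @export
quantify_sample <- function(curve, response, dry_mass_g,
                            extract_volume_ml = 1, dilution_factor = 1,
                            sample_id = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0 || curve$degenerate)
    stop("cannot invert a flat calibration curve")
  if (dry_mass_g <= 0) stop("dry_mass_g must be > 0")
  conc <- (response - curve$intercept) / curve$slope
  data.frame(sample_id = sample_id, analyte = curve$analyte,
             response = response, conc_ug_per_ml = conc,
             ug_per_g = conc * extract_volume_ml * dilution_factor / dry_mass_g,
             below_range = conc < curve$range[1],
             above_range = conc > curve$range[2],
             stringsAsFactors = FALSE)
}

#' Group summary: n, mean, SD, SEM
#'
#' Sample (n-1) standard deviation and `SEM = SD / sqrt(n)`, the layout of a
#' per-group concentration table footer.
#'
#' @param values numeric vector, at least 2 non-missing values.
#' @return list with `n`, `mean`, `sd`, `sem`.
#' @export
group_summary <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("group summary needs at least 2 values")
  s <- stats::sd(v)
  list(n = length(v), mean = mean(v), sd = s, sem = s / sqrt(length(v)))
}

#' Compare two groups of concentrations by t-test
#'
#' Two-sided two-sample t-test, by default on log2-transformed
#' concentrations with pooled variance. `log2 = FALSE, var_equal = FALSE`
#' gives Welch's test on the raw scale — the calibrated variant that
#' reproduces the p-values printed with the bundled fatty-acid dataset (see
#' the methods vignette for the calibration).
#'
#' @param group_a,group_b concentrations (> 0 when `log2 = TRUE`), at least
#'   2 values per group.
#' @param log2 transform before testing (default `TRUE`).
#' @param var_equal pooled variance (default `TRUE`) or Welch.
#' @return The two-sided p-value.
#' @export
compare_groups <- function(group_a, group_b, log2 = TRUE, var_equal = TRUE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (log2) {
    if (any(a <= 0) || any(b <= 0))
      stop("log2 comparison needs strictly positive concentrations")
    a <- base::log2(a); b <- base::log2(b)
  }
  ttest_feature(a, b, var_equal = var_equal)
}

#' @rdname compare_groups
#' @export
compare_groups_log2 <- function(group_a, group_b, var_equal = TRUE) {
  compare_groups(group_a, group_b, log2 = TRUE, var_equal = var_equal)
}
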