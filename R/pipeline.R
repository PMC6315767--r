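#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. A single `seed` feeds
#' all stochastic stages through a deterministic derivation (the stage name
#' is hashed into an offset), so a rerun with the same configuration is
#' reproducible without coupling the stages to each other.
#'
#' @param pairs list of length-2 character vectors of group labels to model;
#'   `NULL` (default) models every unordered pair of biological groups.
#' @param rsd_threshold,max_missing pre-processing thresholds.
#' @param n_ortho,n_folds model settings.
#' @param n_perm permutations for the validation stage (>= 1).
#' @param cascade a [cascade_config()].
#' @param max_overfit,alpha verdict thresholds (see [model_verdict()]).
#' @param seed master seed.
#' @param output_dir optional directory; when given, [run_pipeline()] writes
#'   the report bundle there as CSV/JSON.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pairs = NULL, rsd_threshold = 30,
                            max_missing = 0.20, n_ortho = 1, n_folds = 7,
                            n_perm = 999, cascade = cascade_config(),
                            max_overfit = 0.3, alpha = 0.05,
                            seed = 1L, output_dir = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(pairs = pairs, rsd_threshold = rsd_threshold,
                 max_missing = max_missing, n_ortho = n_ortho,
                 n_folds = n_folds, n_perm = n_perm, cascade = cascade,
                 max_overfit = max_overfit, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Fields mirror the [pipeline_config()] arguments; `pairs` is a list of
#' two-element group-label vectors and `cascade` a mapping of
#' [cascade_config()] arguments.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$pairs)) lst$pairs <- lapply(lst$pairs, unlist)
  if (!is.null(lst$cascade)) lst$cascade <- do.call(cascade_config, lst$cascade)
  do.call(pipeline_config, lst)
}

# deterministic stage seed: master seed + hashed stage name, kept in 32 bits
stage_seed <- function(seed, stage) {
  as.integer((seed + sum(utf8ToInt(stage)) * 7919) %% .Machine$integer.max)
}

#' Run the full biomarker-discovery pipeline
#'
#' QC-RSD and missingness filtering, log2 + Pareto scaling, then for every
#' configured group pair: OPLS-DA fit, cross-validated Q2, permutation test,
#' CV-ANOVA and a validity/significance verdict. The marker filtration
#' cascade runs only for pairs whose model is both valid and significant.
#' Pareto scaling is computed within each pair's own samples (the model's
#' training set), after per-feature half-minimum imputation.
#'
#' @param table a [feature_table()] (with pooled-QC rows) or a path readable
#'   by [read_feature_table()].
#' @param config a [pipeline_config()].
#' @return Object of class `report_bundle`: `rsd_report`, `missing_report`,
#'   `verdicts` (one row per pair), `markers` (named list of
#'   [select_markers()] tables for valid + significant pairs), `counts`
#'   (feature accounting) and `meta` (seed, package version, settings).
#' @export
run_pipeline <- function(table, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(table)) table <- read_feature_table(table)
  stopifnot(inherits(table, "feature_table"))
  if (config$n_perm < 1) stop("n_perm must be >= 1")

  n_in <- length(table$feature_id)
  prep <- preprocess(table, rsd_threshold = config$rsd_threshold,
                     max_missing = config$max_missing)
  n_rsd <- sum(prep$rsd_report$passed)
  n_kept <- length(prep$filtered$feature_id)
  message(sprintf("features: %d detected, %d after RSD filter, %d after missingness filter",
                  n_in, n_rsd, n_kept))

  groups <- unique(table$group[!table$is_qc])
  pairs <- config$pairs
  if (is.null(pairs)) {
    cmb <- utils::combn(groups, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  bad <- unlist(pairs)[!unlist(pairs) %in% groups]
  if (length(bad)) stop("configured groups not in the table: ",
                        paste(unique(bad), collapse = ", "))

  verdicts <- NULL
  markers <- list()
  bio <- biological_samples(prep$filtered)
  for (pr in pairs) {
    label <- paste(pr, collapse = " vs ")
    sub <- subset_table(bio, samples = bio$group %in% pr)
    lg <- log2_transform(suppressWarnings(zeros_to_missing(sub)))
    scaled <- pareto_scale(impute_half_min(lg))
    y <- sub$group
    cvf <- cross_validate(scaled, y, n_ortho = config$n_ortho,
                          n_folds = config$n_folds)
    perm <- permutation_test(scaled, y, n_ortho = config$n_ortho,
                             n_perm = config$n_perm,
                             n_folds = config$n_folds,
                             seed = stage_seed(config$seed,
                                               paste0("permutation:", label)))
    an <- cv_anova(cvf)
    v <- assess_model(cvf, perm, an, max_overfit = config$max_overfit,
                      alpha = config$alpha)
    v <- cbind(pair = label, v, stringsAsFactors = FALSE)
    verdicts <- rbind(verdicts, v)
    message(sprintf("%s: R2 = %.2f, Q2 = %.2f, valid = %s, significant = %s",
                    label, v$r2, v$q2, v$valid, v$significant))
    if (v$valid && v$significant) {
      markers[[label]] <- select_markers(sub, cvf$model, cvf, groups = pr,
                                         config = config$cascade)
    }
  }
  class(verdicts) <- c("model_verdict", "data.frame")
  bundle <- structure(list(
    rsd_report = prep$rsd_report, missing_report = prep$missing_report,
    verdicts = verdicts, markers = markers,
    counts = c(detected = n_in, after_rsd = n_rsd, retained = n_kept),
    meta = list(seed = config$seed,
                package_version = as.character(utils::packageVersion("oplsmark")),
                n_perm = config$n_perm, n_ortho = config$n_ortho,
                n_folds = config$n_folds)
  ), class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  features: %d detected -> %d after QC-RSD -> %d retained\n",
              x$counts["detected"], x$counts["after_rsd"],
              x$counts["retained"]))
  cat("  model verdicts:\n")
  print(as.data.frame(x$verdicts), row.names = FALSE, digits = 3)
  if (length(x$markers)) {
    for (nm in names(x$markers))
      cat(sprintf("  %s: %d markers selected\n", nm,
                  sum(x$markers[[nm]]$selected)))
  } else cat("  no valid + significant pair; marker cascade not run\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Filter reports, verdict table and marker tables as CSV; run metadata as
#' JSON.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$rsd_report, file.path(dir, "rsd_filter.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$missing_report,
                   file.path(dir, "missingness_filter.csv"), row.names = FALSE)
  utils::write.csv(bundle$verdicts, file.path(dir, "model_verdicts.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$markers)) {
    fn <- paste0("markers_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv")
    utils::write.csv(bundle$markers[[nm]], file.path(dir, fn),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
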