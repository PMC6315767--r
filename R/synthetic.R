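#' Configuration for the synthetic feature-table generator
#'
#' Defines a log-normal intensity model that emulates the statistical
#' structure of an untargeted LC-MS faecal-metabolomics study: per-feature
#' baseline intensities on the log2 scale, biological log-scale variance,
#' multiplicative group fold-change effects for a subset of "planted"
#' differential features, pooled-QC technical noise targeting a chosen RSD,
#' and missing values from both a completely-at-random mechanism and
#' low-intensity (below-LOD) censoring.
#'
#' The defaults mirror a six-group paediatric Crohn's disease EEN study
#' design: groups HC, PA..PE with 11/11/10/11/11/11 biological samples,
#' ~600 features, 8 differential features in the pre-treatment (PA) group
#' with fold changes between 0.15 and 20.3, five pooled-QC injections and a
#' 14% technical RSD.
#'
#' @param n_features number of metabolite features.
#' @param groups named integer vector: samples per group label.
#' @param n_differential number of planted differential features
#'   (`<= n_features`).
#' @param fold_changes multiplicative (linear-scale, > 0) group effects for
#'   the differential features; length `n_differential` or 1 (recycled).
#' @param affected_group group label receiving the fold-change effects.
#' @param base_log2_mean_range interval from which per-feature baseline log2
#'   means are drawn uniformly.
#' @param biological_log2_sd biological standard deviation on the log2 scale.
#' @param technical_rsd_percent target percent RSD of the pooled-QC
#'   injections (multiplicative log-normal noise).
#' @param n_qc_pools number of pooled-QC injections.
#' @param missing_rate_mcar fraction in \[0,1\] of entries set missing
#'   completely at random.
#' @param censor_quantile fraction in \[0,1\]; per feature, observed values
#'   below this sample quantile are set missing, emulating below-LOD dropout.
#' @param seed integer seed; the generator is deterministic given the config.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_features = 600,
                             groups = c(HC = 11, PA = 11, PB = 10,
                                        PC = 11, PD = 11, PE = 11),
                             n_differential = 8,
                             fold_changes = c(0.15, 6.54, 0.37, 14.52,
                                              16.18, 20.32, 18.05, 11.88),
                             affected_group = "PA",
                             base_log2_mean_range = c(10, 24),
                             biological_log2_sd = 1,
                             technical_rsd_percent = 14,
                             n_qc_pools = 5,
                             missing_rate_mcar = 0.01,
                             censor_quantile = 0.02,
                             seed = 1L) {
  if (length(fold_changes) == 1L) fold_changes <- rep(fold_changes, n_differential)
  cfg <- list(n_features = as.integer(n_features), groups = groups,
              n_differential = as.integer(n_differential),
              fold_changes = fold_changes,
              affected_group = affected_group,
              base_log2_mean_range = base_log2_mean_range,
              biological_log2_sd = biological_log2_sd,
              technical_rsd_percent = technical_rsd_percent,
              n_qc_pools = as.integer(n_qc_pools),
              missing_rate_mcar = missing_rate_mcar,
              censor_quantile = censor_quantile,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_features < 1L) stop("n_features must be >= 1")
  if (is.null(names(cfg$groups)) || any(names(cfg$groups) == ""))
    stop("groups must be a named vector of per-group sample counts")
  if (any(cfg$groups < 1)) stop("every group needs >= 1 sample")
  if (cfg$n_differential > cfg$n_features)
    stop("n_differential must not exceed n_features")
  if (cfg$n_differential > 0 &&
      length(cfg$fold_changes) != cfg$n_differential)
    stop("fold_changes must have length n_differential (or 1)")
  if (any(cfg$fold_changes <= 0)) stop("fold_changes must be > 0")
  if (cfg$n_differential > 0 && !cfg$affected_group %in% names(cfg$groups))
    stop("affected_group ", cfg$affected_group, " not among the group labels")
  if (cfg$biological_log2_sd < 0) stop("biological_log2_sd must be >= 0")
  if (cfg$technical_rsd_percent < 0) stop("technical_rsd_percent must be >= 0")
  for (f in c("missing_rate_mcar", "censor_quantile")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(f, " must be a fraction in [0,1]")
  }
  invisible(cfg)
}

#' Generate a synthetic feature table with planted ground truth
#'
#' Intensities are drawn on the log2 scale (per-feature baseline from
#' `base_log2_mean_range`, Gaussian noise with sd `biological_log2_sd`);
#' differential features are multiplied by their fold change in the affected
#' group; the matrix is exponentiated back to the raw scale; missingness is
#' applied MCAR first and below-LOD censoring second. Pooled-QC injections
#' (feature-wise biological means plus multiplicative technical noise) are
#' then appended with [generate_qc_pools()].
#'
#' @param config a [synthetic_config()].
#' @param qc logical; append pooled-QC injections (default `TRUE`).
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (data.frame `feature_id`, `affected_group`, `planted_fold_change`, one
#'   row per differential feature).
#' @export
generate_dataset <- function(config, qc = TRUE) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  labels <- rep(names(config$groups), times = config$groups)
  n <- length(labels)
  m <- config$n_features
  fid <- sprintf("F%03d", seq_len(m))
  sid <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s%02d", g, seq_len(config$groups[[g]]))), use.names = FALSE)

  base <- stats::runif(m, config$base_log2_mean_range[1],
                       config$base_log2_mean_range[2])
  log2x <- matrix(stats::rnorm(n * m, sd = config$biological_log2_sd),
                  nrow = n, ncol = m, byrow = FALSE)
  log2x <- sweep(log2x, 2, base, "+")

  diff_idx <- seq_len(config$n_differential)
  if (config$n_differential > 0) {
    in_grp <- labels == config$affected_group
    log2x[in_grp, diff_idx] <- sweep(log2x[in_grp, diff_idx, drop = FALSE],
                                     2, log2(config$fold_changes), "+")
  }
  x <- 2^log2x

  # MCAR dropout, then per-feature low-quantile censoring of what remains
  if (config$missing_rate_mcar > 0) {
    drop <- matrix(stats::runif(n * m) < config$missing_rate_mcar, n, m)
    x[drop] <- NA_real_
  }
  if (config$censor_quantile > 0) {
    for (j in seq_len(m)) {
      obs <- !is.na(x[, j])
      if (sum(obs) < 2) next
      cut <- stats::quantile(x[obs, j], config$censor_quantile,
                             names = FALSE, type = 7)
      x[obs & x[, j] < cut, j] <- NA_real_
    }
  }

  tab <- feature_table(x, group = labels, is_qc = rep(FALSE, n),
                       sample_id = sid, feature_id = fid)
  if (qc && config$n_qc_pools > 0) {
    tab <- generate_qc_pools(tab, n_pools = config$n_qc_pools,
                             technical_rsd_percent = config$technical_rsd_percent,
                             seed = config$seed + 1L)
  }
  truth <- data.frame(
    feature_id = fid[diff_idx],
    affected_group = rep(config$affected_group, config$n_differential),
    planted_fold_change = config$fold_changes[seq_len(config$n_differential)],
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = truth)
}

#' Append pooled-QC injections to a feature table
#'
#' Each QC value is the feature-wise mean of the biological samples times a
#' multiplicative log-normal noise term whose coefficient of variation equals
#' `technical_rsd_percent` / 100 (the noise log-sd is
#' `sqrt(log(1 + cv^2))` with mean correction `-sigma^2/2`, so the expected
#' multiplier is 1 and a zero RSD reproduces the mean exactly).
#'
#' @param table a [feature_table()] with at least one biological sample.
#' @param n_pools number of QC injections to append.
#' @param technical_rsd_percent target percent RSD.
#' @param seed integer seed.
#' @return The `feature_table` with `n_pools` QC-flagged rows appended.
#' @export
generate_qc_pools <- function(table, n_pools = 5, technical_rsd_percent = 14,
                              seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  bio <- !table$is_qc
  if (!any(bio)) stop("the table has no biological samples to pool")
  if (n_pools < 1) stop("n_pools must be >= 1")
  set.seed(seed)
  m <- length(table$feature_id)
  mu <- colMeans(table$intensity[bio, , drop = FALSE], na.rm = TRUE)
  cv <- technical_rsd_percent / 100
  sigma <- sqrt(log1p(cv^2))
  noise <- matrix(exp(stats::rnorm(n_pools * m, mean = -sigma^2 / 2,
                                   sd = sigma)),
                  nrow = n_pools, ncol = m)
  qc <- sweep(noise, 2, mu, "*")
  existing_qc <- sum(table$is_qc)
  qid <- sprintf("QC%02d", existing_qc + seq_len(n_pools))
  feature_table(rbind(table$intensity, qc),
                group = c(table$group, rep("QC", n_pools)),
                is_qc = c(table$is_qc, rep(TRUE, n_pools)),
                sample_id = c(table$sample_id, qid),
                feature_id = table$feature_id,
                annotation = table$annotation)
}
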