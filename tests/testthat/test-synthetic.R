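test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(n_features = 5, n_differential = 8,
                                fold_changes = 2),
               "n_differential")
  expect_error(synthetic_config(n_differential = 1, fold_changes = -2),
               "fold_changes")
  expect_error(synthetic_config(missing_rate_mcar = 1.2), "fraction")
  expect_error(synthetic_config(n_differential = 2, fold_changes = c(2, 2),
                                affected_group = "ZZ"), "affected_group")
})

test_that("generated tables have the configured shape and ground truth", {
  cfg <- synthetic_config(n_features = 100, groups = c(HC = 11, PA = 11),
                          n_differential = 0, fold_changes = numeric(0),
                          n_qc_pools = 5, seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$truth), 0)
  expect_equal(dim(biological_samples(ds$table)$intensity), c(22, 100))
  expect_equal(sum(ds$table$is_qc), 5)

  cfg2 <- synthetic_config(n_features = 40, groups = c(A = 6, B = 7, C = 5),
                           n_differential = 4, fold_changes = 8,
                           affected_group = "B", seed = 5)
  ds2 <- generate_dataset(cfg2)
  expect_equal(nrow(ds2$truth), 4)
  expect_true(all(ds2$truth$planted_fold_change == 8))
  expect_equal(length(ds2$table$sample_id), 6 + 7 + 5 + 5)
})

test_that("generation is bit-identical given the same config and seed", {
  cfg <- synthetic_config(n_features = 50, groups = c(HC = 8, PA = 8),
                          n_differential = 3, fold_changes = 4, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$table$intensity, b$table$intensity)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(synthetic_config(n_features = 50,
                                         groups = c(HC = 8, PA = 8),
                                         n_differential = 3, fold_changes = 4,
                                         seed = 12))
  expect_false(identical(a$table$intensity, c$table$intensity))
})

test_that("QC pools at zero RSD equal the biological feature means exactly", {
  ds <- make_study(seed = 2, n_features = 20, missing_rate_mcar = 0,
                   censor_quantile = 0)
  tab <- biological_samples(ds$table)
  qc <- generate_qc_pools(tab, n_pools = 5, technical_rsd_percent = 0,
                          seed = 9)
  expect_equal(sum(qc$is_qc), 5)
  mu <- colMeans(tab$intensity)
  for (i in which(qc$is_qc))
    expect_equal(unname(qc$intensity[i, ]), unname(mu))
})

test_that("empirical QC RSD matches the requested RSD within sampling error", {
  # 200 replicate QC draws of each feature: RSD estimate has ~5% relative SE
  ds <- make_study(seed = 4, n_features = 30, missing_rate_mcar = 0,
                   censor_quantile = 0)
  tab <- biological_samples(ds$table)
  qc <- generate_qc_pools(tab, n_pools = 200, technical_rsd_percent = 20,
                          seed = 21)
  rsds <- apply(qc$intensity[qc$is_qc, ], 2, compute_rsd)
  expect_equal(mean(rsds), 20, tolerance = 0.05)
  expect_true(all(abs(rsds - 20) < 5))
})

test_that("planted fold changes are recovered in expectation over seeds", {
  fcs <- c(0.25, 4, 16)
  l2 <- matrix(NA_real_, 50, 3)
  for (s in seq_len(50)) {
    ds <- generate_dataset(synthetic_config(
      n_features = 6, groups = c(HC = 11, PA = 11), n_differential = 3,
      fold_changes = fcs, affected_group = "PA", missing_rate_mcar = 0,
      censor_quantile = 0, n_qc_pools = 0, seed = 100 + s), qc = FALSE)
    tab <- ds$table
    pa <- tab$group == "PA"
    for (j in 1:3)
      l2[s, j] <- log2(mean(tab$intensity[pa, j]) /
                         mean(tab$intensity[!pa, j]))
  }
  expect_equal(colMeans(l2), log2(fcs), tolerance = 0.25,
               ignore_attr = TRUE)
})

test_that("missingness fraction matches MCAR plus censoring contribution", {
  cfg <- synthetic_config(n_features = 200, groups = c(HC = 27, PA = 27),
                          n_differential = 0, fold_changes = numeric(0),
                          missing_rate_mcar = 0.10, censor_quantile = 0.05,
                          n_qc_pools = 0, seed = 31)
  ds <- generate_dataset(cfg, qc = FALSE)
  frac <- mean(is.na(ds$table$intensity))
  # expected ~ 0.10 + 0.90 * 0.05 (censoring acts on the observed values)
  expect_equal(frac, 0.10 + 0.90 * 0.05, tolerance = 0.15)
})
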