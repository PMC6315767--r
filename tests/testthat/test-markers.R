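test_that("t-test p-values match the pooled closed form and are symmetric", {
  expect_equal(ttest_feature(c(1, 2, 3), c(1, 2, 3)), 1)
  # pooled t: means 2 vs 3, s2 = 1, t = -1.2247, df = 4
  p <- ttest_feature(c(1, 2, 3), c(2, 3, 4))
  expect_equal(p, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-10)
  expect_equal(round(p, 3), 0.288)
  expect_equal(ttest_feature(c(2, 3, 4), c(1, 2, 3)), p)
  expect_equal(ttest_feature(c(5, 5, 5), c(5, 5)), 1)  # degenerate equal
  expect_equal(ttest_feature(c(5, 5, 5), c(7, 7)), 0)  # degenerate unequal
  expect_error(ttest_feature(c(1), c(1, 2)), "at least 2")
})

test_that("jack-knife CI matches the hand-computed standard error", {
  folds <- c(1.0, 1.2, 0.8, 1.1, 0.9, 1.0, 1.0)
  jk <- jackknife_ci(matrix(folds, ncol = 1), center = 1.0)
  se_hand <- sqrt(6 / 7 * sum((folds - mean(folds))^2))
  expect_equal(jk$se, se_hand)
  expect_equal(jk$ci_low, 1.0 - qt(0.975, 6) * se_hand)
  expect_false(jk$spans_zero)

  # identical folds: zero-width interval away from zero
  jk0 <- jackknife_ci(matrix(rep(0.4, 5), ncol = 1), center = 0.4)
  expect_equal(jk0$se, 0)
  expect_false(jk0$spans_zero)

  # symmetric folds around zero span zero
  jks <- jackknife_ci(matrix(c(-1, 1, -1, 1), ncol = 1), center = 0)
  expect_true(jks$spans_zero)
  expect_error(jackknife_ci(matrix(1, 1, 1)), "at least 2")
})

test_that("BH q-values match hand computation and brute-force step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), "0,1")
  set.seed(77)
  for (i in 1:100) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone: larger p never gets smaller q
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("AUC equals the all-pairs U statistic and is banded correctly", {
  sep <- roc_auc(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$band, "excellent")
  expect_false(sep$excluded)

  set.seed(123)
  for (i in 1:100) {
    a <- sample(0:5, sample(2:8, 1), replace = TRUE)  # ties likely
    b <- sample(0:5, sample(2:8, 1), replace = TRUE)
    expect_equal(roc_auc(a, b)$auc, auc_bruteforce(a, b), tolerance = 1e-12)
  }

  # construct 10 vs 10 groups with exactly k losing pairs: auc = 1 - k/100
  make_groups <- function(k) {
    n_full <- k %/% 10; rem <- k %% 10
    a <- c(rep(0.5, n_full), if (rem) 10 - rem + 0.5,
           rep(100, 10 - n_full - (rem > 0)))
    list(a = a, b = 1:10)
  }
  bands <- vapply(c(5, 15, 25, 35, 45), function(k) {
    g <- make_groups(k)
    res <- roc_auc(g$a, g$b)
    expect_equal(res$auc, 1 - k / 100)
    res$band
  }, character(1))
  expect_identical(bands,
                   c("excellent", "good", "fair", "poor", "failed"))
  expect_true(roc_auc(c(1, 3, 2, 4), c(2, 3, 1, 5))$auc >= 0.5)  # folded
  expect_error(roc_auc(numeric(0), 1), "non-missing")
})

test_that("Q-Q straightness flags normal and bimodal samples correctly", {
  v <- qnorm((1:40 - 0.5) / 40)  # exact normal quantiles
  qq <- qq_normality(v)
  expect_equal(qq$r2, 1, tolerance = 1e-12)
  expect_true(qq$is_normal)
  # strongly bimodal samples fail in nearly all draws
  fails <- vapply(1:100, function(s) {
    set.seed(1200 + s)
    x <- c(rnorm(15, 0, 0.05), rnorm(15, 10, 0.05))
    qq_normality(x)$r2 < 0.95
  }, logical(1))
  expect_gte(mean(fails), 0.95)
  expect_error(qq_normality(rep(3, 10)), "constant")
  expect_error(qq_normality(c(1, 2)), "at least 3")
})

test_that("fold change is the raw-scale mean ratio with log2 reporting", {
  expect_equal(fold_change(c(2, 2), c(2, 2)), list(ratio = 1, log2_ratio = 0))
  expect_equal(fold_change(c(4, 4), c(1, 1)), list(ratio = 4, log2_ratio = 2))
  expect_error(fold_change(c(0, 0), c(1, 1)), "positive")
})

test_that("covariate correlation matches the direct formula", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1)
  y <- c(0.9, 2.8, 2.6, 5.9, 3.7)
  out <- correlate_with_covariate(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_direct, tolerance = 1e-12)
  expect_equal(correlate_with_covariate(x, x)$r, 1)
  sp <- correlate_with_covariate(x, y, method = "spearman")
  expect_equal(sp$r, cor(x, y, method = "spearman"))
  expect_error(correlate_with_covariate(x, rep(1, 5)), "constant")
  expect_error(correlate_with_covariate(c(1, 2), c(3, 4)), "at least 3")
})

cascade_fixture <- function(seed = 1) {
  ds <- make_study(seed = seed)
  prep <- preprocess(ds$table)
  bio <- biological_samples(prep$filtered)
  cv <- cross_validate(prep$scaled, bio$group, n_ortho = 1)
  list(ds = ds, bio = bio, cv = cv)
}

test_that("the cascade drops each feature at its first failing stage", {
  fx <- cascade_fixture(1)
  mk <- select_markers(fx$bio, fx$cv$model, fx$cv, groups = c("PA", "HC"))
  expect_equal(nrow(mk), length(fx$bio$feature_id))
  cfg <- cascade_config()
  # recompute the expected first failing stage from the reported columns
  expected <- vapply(seq_len(nrow(mk)), function(i) {
    if (mk$p_value[i] > cfg$alpha_t) return("t_test")
    if (mk$spans_zero[i]) return("jackknife_ci")
    if (mk$q_value[i] > cfg$alpha_q) return("q_value")
    if (mk$auc[i] < cfg$auc_min) return("auc")
    if (mk$vip_total[i] <= cfg$vip_total_min) return("vip_total")
    NA_character_
  }, character(1))
  expect_identical(unname(mk$drop_stage), unname(expected))
  expect_identical(mk$selected, is.na(mk$drop_stage))
  # ranking: selected markers ranked by descending total VIP
  sel <- mk[mk$selected, ]
  expect_identical(sel$final_rank[order(-sel$vip_total)],
                   sort(sel$final_rank))
  # q-values come from BH over all features entering the cascade, so a
  # feature passing the t stage can still carry q above the cutoff
  expect_equal(mk$q_value, bh_fdr(mk$p_value))
  expect_true(all(mk$q_value >= mk$p_value))
})

test_that("relaxing any single cascade threshold never shrinks the list", {
  fx <- cascade_fixture(2)
  base <- cascade_config()
  sel0 <- select_markers(fx$bio, fx$cv$model, fx$cv, c("PA", "HC"), base)
  picked0 <- sel0$feature_id[sel0$selected]
  relaxed <- list(
    cascade_config(alpha_t = 0.2),
    cascade_config(alpha_q = 0.2),
    cascade_config(auc_min = 0.5),
    cascade_config(vip_total_min = 0.5)
  )
  for (cfg in relaxed) {
    sel <- select_markers(fx$bio, fx$cv$model, fx$cv, c("PA", "HC"), cfg)
    expect_true(all(picked0 %in% sel$feature_id[sel$selected]))
  }
})

test_that("planted markers dominate the selected list on synthetic data", {
  hits <- false_rates <- numeric(5)
  for (s in 1:5) {
    fx <- cascade_fixture(2000 + s)
    mk <- select_markers(fx$bio, fx$cv$model, fx$cv, c("PA", "HC"))
    sel <- mk$feature_id[mk$selected]
    hits[s] <- sum(sel %in% fx$ds$truth$feature_id)
    false_rates[s] <- sum(!sel %in% fx$ds$truth$feature_id)
  }
  expect_gte(mean(hits), 8)
  expect_lte(mean(false_rates), 2)
})

test_that("under the global null the q-stage pass rate honours the FDR level", {
  rates <- vapply(1:40, function(s) {
    ds <- make_study(seed = 3000 + s, n_features = 80, n_diff = 0, fc = 1)
    prep <- preprocess(ds$table)
    bio <- biological_samples(prep$filtered)
    raw <- bio$intensity; raw[raw == 0] <- NA
    la <- bio$group == "PA"
    p <- apply(raw, 2, function(v)
      ttest_feature(log2(v[la]), log2(v[!la])))
    mean(bh_fdr(p) <= 0.05)
  }, numeric(1))
  mc_se <- sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 3 * mc_se)
})

test_that("strict mode enforces the orthogonal-dominance and Q-Q drops", {
  fx <- cascade_fixture(4)
  strict <- cascade_config(require_pred_ge_ortho = TRUE, enforce_qq = TRUE)
  mk <- select_markers(fx$bio, fx$cv$model, fx$cv, c("PA", "HC"), strict)
  lax <- select_markers(fx$bio, fx$cv$model, fx$cv, c("PA", "HC"))
  expect_lte(sum(mk$selected), sum(lax$selected))
  expect_true(all(mk$not_biomarker_relevant ==
                    (mk$vip_ortho > mk$vip_pred)))
})
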