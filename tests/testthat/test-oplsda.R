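random_case <- function(seed, n = 20, m = 50) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  y <- rep(c("A", "B"), length.out = n)
  list(x = x, y = y)
}

test_that("with no orthogonal component the fit equals NIPALS PLS1", {
  for (s in 1:20) {
    cs <- random_case(s)
    m0 <- oplsda(cs$x, cs$y, n_ortho = 0)
    xc <- sweep(cs$x, 2, colMeans(cs$x))
    d <- ifelse(cs$y == "B", 1, -1); d <- d - mean(d)
    or <- nipals_pls1(xc, d)
    sgn <- sign(sum(or$w * m0$weights))
    expect_lt(max(abs(m0$weights - sgn * or$w)), 1e-10)
    expect_lt(max(abs(m0$scores - sgn * or$t)), 1e-10)
  }
})

test_that("the predictive component matches an external PLS implementation", {
  cs <- random_case(99)
  m0 <- oplsda(cs$x, cs$y, n_ortho = 0)
  d <- ifelse(cs$y == "B", 1, -1); d <- d - mean(d)
  pm <- mixOmics::pls(cs$x, d, ncomp = 1, mode = "regression", scale = FALSE)
  t_mix <- unname(pm$variates$X[, 1])
  dev <- min(max(abs(m0$scores - t_mix)), max(abs(m0$scores + t_mix)))
  expect_lt(dev, 1e-8)
})

test_that("predictive and orthogonal scores are orthogonal by construction", {
  for (s in 1:5) {
    cs <- random_case(s + 40)
    m <- oplsda(cs$x, cs$y, n_ortho = 3)
    for (k in seq_len(m$n_ortho))
      expect_lt(abs(sum(m$scores * m$ortho_scores[, k])), 1e-8)
    expect_equal(sqrt(sum(m$weights^2)), 1)
    if (m$n_ortho > 0)
      expect_equal(unname(sqrt(colSums(m$ortho_weights^2))),
                   rep(1, m$n_ortho))
  }
})

test_that("decomposition is complete with exact variance bookkeeping", {
  for (n_ortho in 0:3) {
    cs <- random_case(60 + n_ortho)
    m <- oplsda(cs$x, cs$y, n_ortho = n_ortho)
    xc <- sweep(cs$x, 2, colMeans(cs$x))
    recon <- tcrossprod(m$scores, m$loading) + m$residual_x
    if (m$n_ortho > 0)
      recon <- recon + tcrossprod(m$ortho_scores, m$ortho_loadings)
    expect_lt(max(abs(xc - recon)), 1e-8)
    expect_lt(abs(sum(m$residual_x^2) - (1 - m$r2x_cum) * m$ss_x), 1e-8)
  }
})

test_that("a separable toy problem is separated by the sign of t[1]", {
  x <- rbind(c(0, 0, 1), c(0.5, 0.2, 0.8),
             c(4, 4, 5), c(4.5, 3.8, 4.6))
  y <- c("low", "low", "high", "high")
  m <- oplsda(x, y, n_ortho = 0)
  expect_equal(length(unique(sign(m$scores)[y == "low"])), 1)
  expect_true(all(sign(m$scores)[y == "low"] != sign(m$scores)[y == "high"]))
  expect_identical(predict(m, x, type = "class"), y)
})

test_that("results are invariant to class relabelling (up to sign)", {
  cs <- random_case(77)
  m1 <- oplsda(cs$x, cs$y)
  y2 <- ifelse(cs$y == "A", "zebra", "aardvark")  # reverses level order
  m2 <- oplsda(cs$x, y2)
  expect_equal(m1$r2y, m2$r2y)
  expect_equal(m1$r2x_cum, m2$r2x_cum)
  expect_lt(min(max(abs(m1$scores - m2$scores)),
                max(abs(m1$scores + m2$scores))), 1e-10)
  cv1 <- cross_validate(cs$x, cs$y)
  cv2 <- cross_validate(cs$x, y2)
  expect_equal(cv1$Q2, cv2$Q2)
})

test_that("the fit is deterministic and rejects bad input", {
  cs <- random_case(5)
  expect_identical(oplsda(cs$x, cs$y)$weights, oplsda(cs$x, cs$y)$weights)
  expect_error(oplsda(cs$x, rep("A", 20)), "2 classes")
  expect_error(oplsda(cs$x, rep(c("A", "B", "C"), length.out = 20)),
               "2 classes")
  xna <- cs$x; xna[1, 1] <- NA
  expect_error(oplsda(xna, cs$y), "missing")
})

test_that("VIP identities: unit mean square, symmetry, equivariance", {
  cs <- random_case(31)
  m <- oplsda(cs$x, cs$y, n_ortho = 2)
  v <- vip(m)
  expect_equal(mean(v$vip_pred^2), 1, tolerance = 1e-10)
  expect_equal(mean(v$vip_total^2), 1, tolerance = 1e-10)
  expect_equal(mean(v$vip_ortho^2), 1, tolerance = 1e-10)

  # equal weights: every feature equally important
  d <- ifelse(cs$y == "B", 1, -1); d <- d - mean(d)
  xeq <- d %*% t(rep(1, 5)) + 0  # identical columns
  meq <- oplsda(xeq, cs$y, n_ortho = 0)
  expect_equal(vip(meq)$vip_pred, rep(1, 5), tolerance = 1e-10)

  # permuting features permutes VIP identically
  perm <- sample(ncol(cs$x))
  mp <- oplsda(cs$x[, perm], cs$y, n_ortho = 2)
  vp <- vip(mp)
  expect_equal(vp$vip_total, v$vip_total[perm], tolerance = 1e-10)
  expect_equal(vp$vip_pred, v$vip_pred[perm], tolerance = 1e-10)

  # n_ortho = 0: orthogonal part zero, ratio infinite
  v0 <- vip(oplsda(cs$x, cs$y, n_ortho = 0))
  expect_true(all(v0$vip_ortho == 0))
  expect_true(all(is.infinite(v0$vip_ratio)))
})

test_that("coef() reproduces predict() and new-sample projection works", {
  cs <- random_case(12)
  m <- oplsda(cs$x, cs$y, n_ortho = 1)
  b <- coef(m)
  manual <- c(sweep(cs$x, 2, m$x_center) %*% b) + attr(b, "intercept")
  expect_equal(manual, predict(m, cs$x, type = "response"), tolerance = 1e-12)
  expect_equal(predict(m, cs$x, type = "response"), fitted(m),
               tolerance = 1e-12)
  sc <- predict(m, cs$x, type = "scores")
  expect_equal(sc$t, m$scores, tolerance = 1e-12)
  expect_equal(sc$t_ortho, m$ortho_scores, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(residuals(m), m$dummy - fitted(m), tolerance = 1e-12)
})
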