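# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms / direct enumeration.

# classical NIPALS PLS1 on an already-centered X and response
nipals_pls1 <- function(X, y, tol = 1e-12, maxit = 500) {
  u <- y
  w_old <- rep(Inf, ncol(X))
  w <- tt <- q <- NULL
  for (i in seq_len(maxit)) {
    w <- crossprod(X, u)
    w <- w / sqrt(sum(w^2))
    tt <- c(X %*% w)
    q <- sum(y * tt) / sum(tt^2)
    u <- y  # single response: u stays y
    if (sum((w - w_old)^2) < tol) break
    w_old <- w
  }
  list(w = c(w), t = tt, c = q)
}

# Benjamini-Hochberg by direct step-up enumeration: q_i is the smallest
# level alpha (among the finitely many values where the rejection set can
# change) at which the step-up procedure rejects p_i.
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  # the 1e-9 slack only absorbs binary round-off when alpha is itself a
  # reconstructed threshold m * p_(j) / j
  k <- which(ps <= seq_len(m) / m * alpha + 1e-9)
  if (!length(k)) return(rep(FALSE, m))
  p <= ps[max(k)]
}

bh_oracle <- function(p) {
  m <- length(p)
  cand <- sort(unique(c(outer(p, seq_len(m), function(pp, j) pmin(1, m * pp / j)))))
  vapply(seq_along(p), function(i) {
    ok <- cand[vapply(cand, function(a) bh_stepup_reject(p, a)[i], logical(1))]
    if (length(ok)) min(ok) else 1
  }, numeric(1))
}

# AUC by brute-force all-pairs counting: wins + half ties
auc_bruteforce <- function(a, b) {
  wins <- ties <- 0
  for (x in a) for (y in b) {
    if (x > y) wins <- wins + 1 else if (x == y) ties <- ties + 1
  }
  u <- (wins + ties / 2) / (length(a) * length(b))
  max(u, 1 - u)
}

# small two-group planted-effect study used across tests
make_study <- function(seed, n_features = 100, n_diff = 10, fc = 16,
                       rsd = 10, n_per_group = 11, ...) {
  cfg <- synthetic_config(
    n_features = n_features, groups = c(HC = n_per_group, PA = n_per_group),
    n_differential = n_diff, fold_changes = fc, affected_group = "PA",
    technical_rsd_percent = rsd, seed = seed, ...
  )
  generate_dataset(cfg)
}
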