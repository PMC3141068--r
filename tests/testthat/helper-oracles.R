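# Independent oracles used across the test files.  These deliberately share
# no code with the package implementation.

# Iterative NIPALS PLS1: first latent component of X against a single y.
pls1_nipals <- function(X, y, tol = 1e-12, max_iter = 500) {
  u <- y
  w_old <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    w <- drop(crossprod(X, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    c <- sum(t * y) / sum(t^2)
    u_new <- y * c / max(c^2, .Machine$double.eps)
    if (sqrt(sum((w - w_old)^2)) < tol) break
    w_old <- w
    u <- u_new
  }
  list(w = w, t = t, c = c, fitted = t * c)
}

# Element-wise sample covariance between a score vector and each column.
cov_brute <- function(t, X) {
  n <- length(t)
  tc <- t - mean(t)
  apply(X, 2, function(x) sum(tc * (x - mean(x))) / (n - 1))
}

# Textbook Wilson score bounds (proportion scale).
wilson_direct <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  (p + z^2 / (2 * n) + c(-1, 1) * z *
     sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
}

# Weighted kappa by explicit double sums over a C x C contingency table.
kappa_double_sum <- function(tab, power = 1) {
  C <- nrow(tab)
  n <- sum(tab)
  num <- den <- 0
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      v <- (abs(i - j) / (C - 1))^power
      num <- num + v * tab[i, j] / n
      den <- den + v * sum(tab[i, ]) * sum(tab[, j]) / n^2
    }
  }
  1 - num / den
}

# Exhaustive threshold sweep: smallest threshold whose specificity on the
# negative scores reaches the target, trying every achievable cut.
sweep_threshold <- function(neg, target_pct) {
  cands <- sort(unique(c(neg, min(neg) - 1)))
  for (thr in cands) {
    if (100 * mean(neg <= thr) >= target_pct) return(thr)
  }
  max(neg)
}

# Small AD/CTL-only cohort for fast pipeline tests.
tiny_cohort <- function(seed = 1, effect_scale = 1.5, n_ad = 21, n_ctl = 21,
                        ...) {
  generate_cohort(cohort_spec(n_ad = n_ad, n_ctl = n_ctl, n_mci_conv = 0,
                              n_mci_stable = 0, effect_scale = effect_scale,
                              seed = seed, ...))
}

# Correlation matrix of the assembled features as documented: exchangeable
# block_rho within the template-active and template-null subsets of each
# block, attenuated off the diagonal by the per-hemisphere noise share.
documented_feature_cov <- function(rho = 0.3, side_frac = 0.2,
                                   noise_sd = 1) {
  tpl <- atrophy_effect_template()
  R <- diag(57)
  for (blk in c("thickness", "volume")) {
    for (active in c(TRUE, FALSE)) {
      idx <- which(tpl$block == blk & (tpl$sign != 0) == active)
      if (length(idx) > 1) R[idx, idx] <- rho + diag(1 - rho, length(idx))
    }
  }
  core <- noise_sd^2 - (side_frac * noise_sd)^2 / 2
  core * R + (side_frac * noise_sd)^2 / 2 * diag(57)
}
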