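scaled_toy <- function(n = 40, p = 6, seed = 1, shift = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c("AD", "CTL"), length.out = n)
  X[y == "AD", 1] <- X[y == "AD", 1] + shift
  list(X = apply_scaler(X, fit_scaler(X)), y = y)
}

test_that("predictive component equals NIPALS PLS1 when n_ortho = 0", {
  for (seed in 1:5) {
    d <- scaled_toy(seed = seed)
    fit <- fit_opls(d$X, d$y, n_ortho = 0)
    orc <- pls1_nipals(d$X, ifelse(d$y == "AD", 1, -1))
    expect_gt(abs(cor(fit$t, orc$t)), 1 - 1e-10)
    expect_equal(abs(fit$t), abs(orc$t), tolerance = 1e-8)
    expect_equal(predict(fit, d$X), orc$fitted, tolerance = 1e-8)
  }
})

test_that("weights are unit norm and oriented toward the positive class", {
  d <- scaled_toy(seed = 2)
  fit <- fit_opls(d$X, d$y, n_ortho = 1)
  expect_equal(sum(fit$w^2), 1, tolerance = 1e-12)
  expect_gt(mean(fit$t[d$y == "AD"]), mean(fit$t[d$y == "CTL"]))
})

test_that("single-predictor models explain all of X", {
  d <- scaled_toy(p = 1, seed = 3)
  fit <- fit_opls(d$X, d$y, n_ortho = 0)
  expect_equal(fit$R2X, 1.0, tolerance = 1e-12)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(10)
  X <- matrix(rnorm(60 * 12), 60)
  X[, 2:6] <- X[, 2:6] + 2 * X[, 1]   # correlated structure
  colnames(X) <- paste0("f", 1:12)
  y <- rep(c("AD", "CTL"), each = 30)
  X[y == "AD", 7] <- X[y == "AD", 7] + 1.5
  Xs <- apply_scaler(X, fit_scaler(X))
  for (no in 1:3) {
    fit <- fit_opls(Xs, y, n_ortho = no)
    ips <- abs(crossprod(fit$t, fit$T_o))
    expect_true(all(ips <= 1e-8))
    expect_true(fit$R2X >= 0 && fit$R2X <= 1)
  }
})

test_that("an orthogonal filter restores predictive correlation", {
  # a y-orthogonal factor whose feature-space loading overlaps the
  # predictive direction contaminates the unfiltered scores; one
  # orthogonal component removes it
  set.seed(11)
  n <- 80
  y <- rep(c("AD", "CTL"), each = n / 2)
  yv <- ifelse(y == "AD", 1, -1)
  fac <- rnorm(n)
  fac <- fac - yv * sum(fac * yv) / sum(yv^2)
  X <- outer(yv, c(1, 1, 1, 1, 0, 0)) + outer(fac, c(0, 2, 2, 4, 4, 0)) +
    matrix(rnorm(n * 6, sd = 0.3), n)
  colnames(X) <- paste0("f", 1:6)
  Xs <- apply_scaler(X, fit_scaler(X))
  r_raw <- cor(fit_opls(Xs, y, n_ortho = 0)$t, yv)
  r_filt <- cor(fit_opls(Xs, y, n_ortho = 1)$t, yv)
  expect_gt(r_filt, r_raw + 0.1)
  expect_gt(r_filt, 0.9)
})

test_that("Q2 follows the PRESS/SSY definition", {
  expect_equal(q_squared(c(1, -1, 1, -1), c(1, -1, 1, -1)), 1.0)
  y <- c(2, 4, 6, 8)
  expect_equal(q_squared(y, rep(mean(y), 4)), 0.0)
  expect_equal(q_squared(c(1, -1, 1, -1), c(0.5, -0.5, 0.5, -0.5)), 0.75)
  expect_error(q_squared(rep(1, 4), rep(1, 4)), "SSY")
  expect_error(q_squared(1:3, 1:4), "length")
})

test_that("predictions sit on the coded scale with midpoint zero", {
  d <- scaled_toy(seed = 6, shift = 2)
  fit <- fit_opls(d$X, d$y, n_ortho = 0)
  # subject exactly at the training feature mean predicts exactly 0
  expect_equal(unname(predict(fit, matrix(0, 1, ncol(d$X),
                                          dimnames = list(NULL, colnames(d$X))))),
               0, tolerance = 1e-10)
  pred <- predict(fit, d$X)
  expect_gt(mean(pred[d$y == "AD"]), 0)
  expect_lt(mean(pred[d$y == "CTL"]), 0)
  # consistent column permutation leaves predictions unchanged
  perm <- sample(ncol(d$X))
  fit_p <- fit_opls(d$X[, perm], d$y, n_ortho = 0)
  expect_equal(predict(fit_p, d$X[, perm]), pred, tolerance = 1e-10)
})

test_that("cross-validation leaves every subject out exactly once", {
  coh <- tiny_cohort(seed = 12)
  X <- assemble_features(coh)
  cv <- cross_validate(X, coh$group, k = 7)
  expect_equal(sort(unique(cv$fold)), 1:7)
  expect_equal(length(cv$fold), nrow(X))
  for (cl in c("AD", "CTL")) {
    sizes <- table(cv$fold[coh$group == cl])
    expect_lte(max(sizes) - min(sizes), 1)  # class-balanced folds
  }
  expect_error(cross_validate(X, coh$group, k = 30), "at least k")
  expect_error(assign_folds(rep("A", 10), k = 1), "at least 2")
})

test_that("a perfect predictor column yields Q2 near one", {
  set.seed(13)
  y <- rep(c("AD", "CTL"), each = 21)
  X <- cbind(signal = ifelse(y == "AD", 1, -1) + rnorm(42, sd = 0.01),
             noise = rnorm(42))
  cv <- cross_validate(X, y, k = 7)
  expect_gt(cv$q2y, 0.95)
})

test_that("Q2 is invariant to subject ordering", {
  coh <- tiny_cohort(seed = 14)
  X <- assemble_features(coh)
  cv1 <- cross_validate(X, coh$group, k = 7)
  set.seed(1)
  perm <- sample(nrow(X))
  cv2 <- cross_validate(X[perm, ], coh$group[perm], k = 7)
  expect_equal(cv2$q2y, cv1$q2y, tolerance = 1e-12)
})

test_that("covariance loadings equal the brute-force sample covariance", {
  set.seed(15)
  X <- matrix(rnorm(10 * 5), 10, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("AD", "CTL"), each = 5)
  Xs <- apply_scaler(X, fit_scaler(X))
  fit <- fit_opls(Xs, y, n_ortho = 0)
  expect_equal(covariance_loadings(fit, Xs), cov_brute(fit$t, Xs),
               tolerance = 1e-10)
  # a column equal to the score itself has covariance var(t); a column
  # residualized against the score has covariance exactly zero
  resid <- rnorm(10)
  resid <- resid - mean(resid)
  tc <- fit$t - mean(fit$t)
  resid <- resid - tc * sum(resid * tc) / sum(tc^2)
  extra <- cbind(t_copy = fit$t, orth = resid)
  cl <- covariance_loadings(fit, cbind(Xs, extra))
  expect_equal(cl[["t_copy"]], var(fit$t), tolerance = 1e-10)
  expect_equal(cl[["orth"]], 0, tolerance = 1e-10)
})

test_that("jack-knife intervals collapse when folds agree", {
  fake <- structure(list(
    k = 7L,
    fold_loadings = matrix(rep(c(1, -2), each = 7), 7,
                           dimnames = list(NULL, c("a", "b"))),
    full_loadings = c(a = 1, b = -2)
  ), class = "opls_cv")
  ji <- jackknife_intervals(fake)
  expect_equal(ji$lower, ji$upper)
  expect_equal(ji$covariance, c(1, -2))
  expect_true(all(ji$reliable))
  fake$k <- 2L
  expect_error(jackknife_intervals(fake), "3 folds")
})

test_that("orthogonal-component selection finds constructed structure", {
  set.seed(16)
  n <- 84
  y <- rep(c("AD", "CTL"), each = n / 2)
  yv <- ifelse(y == "AD", 1, -1)
  # pure response + white noise: nothing orthogonal to remove
  X_plain <- outer(yv, rep(1, 6)) + matrix(rnorm(n * 6, sd = 0.8), n)
  colnames(X_plain) <- paste0("f", 1:6)
  expect_equal(select_n_ortho(X_plain, y, max_ortho = 3), 0)
  # one strong y-orthogonal factor, overlapping the predictive direction
  # in feature space, degrades the unfiltered model
  fac <- rnorm(n)
  fac <- fac - yv * sum(fac * yv) / sum(yv^2)
  X_o <- outer(yv, c(1, 1, 1, 1, 0, 0)) + outer(fac, c(0, 2, 2, 4, 4, 0)) +
    matrix(rnorm(n * 6, sd = 0.15), n)
  colnames(X_o) <- paste0("f", 1:6)
  expect_equal(select_n_ortho(X_o, y, max_ortho = 3), 1)
  expect_equal(select_n_ortho(X_o, y, max_ortho = 0), 0)
})

test_that("models serialize to JSON and restore identically", {
  coh <- tiny_cohort(seed = 17)
  X <- assemble_features(coh)
  sc <- fit_scaler(X)
  fit <- fit_opls(apply_scaler(X, sc), coh$group, n_ortho = 1, scaler = sc)
  path <- file.path(tempdir(), "opls_model.json")
  write_opls(fit, path)
  back <- read_opls(path)
  expect_equal(back$w, fit$w, tolerance = 1e-12)
  expect_equal(back$coding, fit$coding)
  expect_equal(back$n_ortho, fit$n_ortho)
  expect_equal(predict(back, X, raw = TRUE), predict(fit, X, raw = TRUE),
               tolerance = 1e-10)
  unlink(path)
})

test_that("degenerate responses are rejected", {
  d <- scaled_toy(seed = 18)
  expect_error(fit_opls(d$X, rep("AD", nrow(d$X))), "two classes")
  expect_error(fit_opls(d$X, d$y, n_ortho = -1), "non-negative")
  expect_error(fit_opls(d$X[, 1, drop = FALSE], d$y, n_ortho = 1),
               "rank deficiency")
})
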