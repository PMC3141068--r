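# OPLS-DA engine -------------------------------------------------------------
#
# Orthogonal projections to latent structures for a single binary response:
# y-orthogonal variation is removed from X component by component, then one
# predictive PLS component is fitted to the filtered matrix.  With zero
# orthogonal components the predictive component coincides with the first
# NIPALS PLS1 component.

.code_classes <- function(y, positive = "AD") {
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2)
    stop("response must contain exactly two classes, got: ",
         paste(lev, collapse = ", "))
  if (!positive %in% lev)
    stop("positive class '", positive, "' not present in response")
  negative <- setdiff(lev, positive)
  coded <- ifelse(y == positive, 1, -1)
  list(coded = coded, coding = stats::setNames(c(1, -1),
                                               c(positive, negative)))
}

#' Fit an OPLS-DA model
#'
#' @param X Numeric matrix (subjects x features), already mean-centred and
#'   unit-variance scaled (see [fit_scaler()]).
#' @param y Class labels (two classes).
#' @param n_ortho Number of y-orthogonal components to remove (>= 0).
#' @param positive Label coded +1; the other class is coded -1.  The
#'   predictive weight vector is oriented so the positive class has positive
#'   mean score.
#' @param scaler Optional `uv_scaler` used on the training data; stored so
#'   that [predict.opls_model()] and [transfer_predict()] can scale new raw
#'   data identically.
#' @return An object of class `opls_model`: predictive weights `w` (unit
#'   norm), loadings `p`, scores `t`, y-loading `c`, orthogonal `W_o`, `P_o`,
#'   `T_o`, `n_ortho`, class `coding`, `R2X` and component-wise `R2X_comp`.
#' @export
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(40 * 5), 40))
#' y <- rep(c("AD", "CTL"), each = 20)
#' X[y == "AD", 1] <- X[y == "AD", 1] + 1
#' fit <- fit_opls(apply_scaler(X, fit_scaler(X)), y, n_ortho = 0)
#' fit$R2X
fit_opls <- function(X, y, n_ortho = 0, positive = "AD", scaler = NULL) {
  X <- as.matrix(X)
  cl <- .code_classes(y, positive)
  yv <- cl$coded
  if (nrow(X) != length(yv)) stop("X and y dimensions do not match")
  if (n_ortho < 0 || n_ortho != round(n_ortho))
    stop("'n_ortho' must be a non-negative integer")
  p <- ncol(X)
  ssx <- sum(X^2)
  if (ssx <= 0) stop("X has no variance; was it centred correctly?")

  w <- crossprod(X, yv)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("response is orthogonal to every feature")
  w <- w / nw

  Wo <- Po <- matrix(0, p, 0)
  To <- matrix(0, nrow(X), 0)
  r2_ortho <- numeric(0)
  Xr <- X
  for (j in seq_len(n_ortho)) {
    t_j <- Xr %*% w
    p_j <- crossprod(Xr, t_j) / sum(t_j^2)
    wo <- p_j - c(crossprod(w, p_j)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10)
      stop("rank deficiency: no y-orthogonal variation left for component ",
           j)
    wo <- wo / nwo
    to <- Xr %*% wo
    po <- crossprod(Xr, to) / sum(to^2)
    Xr <- Xr - to %*% t(po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
    r2_ortho <- c(r2_ortho, sum(to^2) * sum(po^2) / ssx)
  }
  t_pred <- Xr %*% w
  if (sum(t_pred^2) < 1e-12)
    stop("rank deficiency: predictive component has zero variance")
  # orient so the positive class sits on the positive side of the score axis
  if (mean(t_pred[yv == 1]) < mean(t_pred[yv == -1])) {
    w <- -w
    t_pred <- -t_pred
  }
  p_pred <- crossprod(Xr, t_pred) / sum(t_pred^2)
  c_load <- sum(yv * t_pred) / sum(t_pred^2)
  r2_pred <- sum(t_pred^2) * sum(p_pred^2) / ssx

  structure(list(
    w = drop(w), p = drop(p_pred), t = drop(t_pred), c = c_load,
    W_o = Wo, P_o = Po, T_o = To, n_ortho = as.integer(n_ortho),
    coding = cl$coding, R2X = min(1, r2_pred + sum(r2_ortho)),
    R2X_comp = c(predictive = r2_pred, orthogonal = r2_ortho),
    features = colnames(X), train_ids = rownames(X), scaler = scaler
  ), class = "opls_model")
}

#' Predict class values from an OPLS-DA model
#'
#' New observations are passed through the model's orthogonal filter and
#' projected on the predictive component; the returned value lives on the
#' +1/-1 coded class scale, so the classification threshold is the coded
#' midpoint 0 (a subject exactly at the training feature mean predicts 0).
#'
#' @param object An `opls_model`.
#' @param newdata Matrix of new observations on the same (scaled) feature
#'   scale as the training data.  If the model stores a scaler and `raw =
#'   TRUE`, raw features are scaled first.
#' @param raw Apply the stored training scaler to `newdata` before
#'   projecting.
#' @param ... Unused.
#' @return Numeric vector of predicted class values.
#' @export
predict.opls_model <- function(object, newdata, raw = FALSE, ...) {
  Xn <- as.matrix(newdata)
  if (raw) {
    if (is.null(object$scaler)) stop("model stores no training scaler")
    Xn <- apply_scaler(Xn, object$scaler)
  }
  if (!is.null(colnames(Xn)) && !identical(colnames(Xn), object$features))
    stop("feature names do not match the training features")
  if (ncol(Xn) != length(object$w))
    stop("feature count does not match the training features")
  for (j in seq_len(object$n_ortho)) {
    to <- Xn %*% object$W_o[, j]
    Xn <- Xn - to %*% t(object$P_o[, j])
  }
  drop(Xn %*% object$w) * object$c
}

#' Cross-validated predictability Q2(Y)
#'
#' `1 - PRESS / SSY`, where `PRESS = sum((y - y_hat)^2)` over left-out
#' predictions and `SSY` is the total variation of the coded response about
#' its mean.  1 for perfect prediction, 0 for a model no better than the
#' response mean, unbounded below.
#'
#' @param y_actual Coded response values.
#' @param y_pred_cv Cross-validated predictions on the same scale.
#' @return Q2(Y), a scalar.
#' @export
#' @examples
#' q_squared(c(1, -1, 1, -1), c(0.5, -0.5, 0.5, -0.5))  # 0.75
q_squared <- function(y_actual, y_pred_cv) {
  if (length(y_actual) != length(y_pred_cv))
    stop("'y_actual' and 'y_pred_cv' must have the same length")
  ssy <- sum((y_actual - mean(y_actual))^2)
  if (ssy <= 0) stop("SSY is zero: response has no variation")
  1 - sum((y_actual - y_pred_cv)^2) / ssy
}

#' Deterministic class-interleaved fold assignment
#'
#' Subjects are ordered by class and dealt round-robin into `k` folds within
#' each class, guaranteeing class balance across folds and a
#' subject-order-invariant Q2 when the within-class order is fixed.  With a
#' `seed`, the within-class order is shuffled first.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Optional shuffle seed.
#' @param ids Optional subject identifiers; when given, the within-class
#'   deal order follows `order(ids)`, making each subject's fold independent
#'   of row order.
#' @return Integer fold id (1..k) per subject.
#' @export
assign_folds <- function(y, k = 7, seed = NULL, ids = NULL) {
  if (k < 2) stop("'k' must be at least 2")
  if (any(table(y) < k))
    stop("every class must have at least k = ", k, " members")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cl in sort(unique(as.character(y)))) {
    idx <- which(y == cl)
    if (!is.null(ids)) idx <- idx[order(ids[idx])]
    if (!is.null(seed)) idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Seven-fold cross-validation of an OPLS-DA model
#'
#' Each fold is left out once; the scaler is refitted on the training folds
#' by default (set `simca_style = TRUE` to scale the full matrix once, as
#' chemometrics packages traditionally do), the model refitted, and the
#' left-out subjects predicted.  Per-fold covariance loadings are retained
#' for jack-knifing.
#'
#' @param X Raw (unscaled) feature matrix, subjects x features.
#' @param y Class labels (two classes).
#' @param k Number of folds (default 7).
#' @param n_ortho Orthogonal components per fold model.
#' @param positive Positive-class label (coded +1).
#' @param simca_style Scale the full matrix once instead of per fold.
#' @param shuffle_seed Optional seed for shuffled fold assignment; default
#'   is the deterministic class-interleaved scheme.
#' @return An object of class `opls_cv`: `fold`, `y_coded`, `y_pred`
#'   (cross-validated), `q2y`, `full_model` (fitted on all subjects, with
#'   its scaler), `full_loadings`, `fold_loadings` (k x features), `k`.
#' @export
cross_validate <- function(X, y, k = 7, n_ortho = 0, positive = "AD",
                           simca_style = FALSE, shuffle_seed = NULL) {
  X <- as.matrix(X)
  cl <- .code_classes(y, positive)
  fold <- assign_folds(y, k, seed = shuffle_seed, ids = rownames(X))
  y_pred <- numeric(nrow(X))
  fold_loadings <- matrix(NA_real_, k, ncol(X),
                          dimnames = list(NULL, colnames(X)))
  global_scaler <- fit_scaler(X)
  for (f in seq_len(k)) {
    tr <- fold != f
    scaler <- if (simca_style) global_scaler else
      fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(X[tr, , drop = FALSE], scaler)
    m <- fit_opls(Xtr, y[tr], n_ortho = n_ortho, positive = positive,
                  scaler = scaler)
    y_pred[!tr] <- predict(m, apply_scaler(X[!tr, , drop = FALSE], scaler))
    fold_loadings[f, ] <- covariance_loadings(m, Xtr)
  }
  full_scaler <- global_scaler
  Xs <- apply_scaler(X, full_scaler)
  full_model <- fit_opls(Xs, y, n_ortho = n_ortho, positive = positive,
                         scaler = full_scaler)
  structure(list(
    fold = fold, y_coded = cl$coded, y_pred = y_pred,
    q2y = q_squared(cl$coded, y_pred),
    full_model = full_model,
    full_loadings = covariance_loadings(full_model, Xs),
    fold_loadings = fold_loadings, k = as.integer(k),
    subject_ids = rownames(X)
  ), class = "opls_cv")
}

#' Covariance loadings of the predictive component
#'
#' The sample covariance (n - 1 denominator) between the predictive score
#' vector and each centred feature column: the quantity plotted on the
#' y-axis of the loading plot to rank regions by their contribution to
#' group separation.
#'
#' @param model An `opls_model`.
#' @param X The (scaled/centred) matrix the model was fitted to.
#' @return Named numeric vector, one covariance per feature.
#' @export
covariance_loadings <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(model$t)) stop("X does not match the model's scores")
  drop(stats::cov(model$t, X))
}

#' Jack-knifed confidence intervals for covariance loadings
#'
#' Uses the k cross-validation submodels as delete-a-group jack-knife
#' pseudo-replicates: `SE_j = sqrt(((k-1)/k) * sum_m (theta_mj -
#' mean_m(theta_mj))^2)` and `CI = theta_j +/- t_{1-alpha/2, k-1} * SE_j`,
#' where `theta_j` is the full-model covariance loading.  A feature whose
#' interval excludes zero is flagged reliable.
#'
#' @param cv_result An `opls_cv` from [cross_validate()].
#' @param level Confidence level (default 0.95).
#' @return A data.frame: `feature`, `covariance`, `lower`, `upper`,
#'   `reliable`.
#' @export
jackknife_intervals <- function(cv_result, level = 0.95) {
  if (!inherits(cv_result, "opls_cv")) stop("need an 'opls_cv' object")
  k <- cv_result$k
  if (k < 3) stop("jack-knifing needs at least 3 folds")
  fl <- cv_result$fold_loadings
  se <- sqrt(((k - 1) / k) * colSums(sweep(fl, 2, colMeans(fl))^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  est <- cv_result$full_loadings
  lower <- est - tq * se
  upper <- est + tq * se
  data.frame(
    feature = names(est), covariance = unname(est),
    lower = unname(lower), upper = unname(upper),
    reliable = unname(lower > 0 | upper < 0),
    stringsAsFactors = FALSE
  )
}

#' Choose the number of orthogonal components
#'
#' Starting from none, an orthogonal component is added as long as it
#' improves cross-validated Q2(Y) by at least `min_gain`; the first
#' non-improving count stops the search.  Deterministic given the
#' deterministic fold assignment.
#'
#' @param X Raw feature matrix.
#' @param y Class labels.
#' @param max_ortho Upper bound on the count (default 5).
#' @param min_gain Minimum Q2 improvement to accept a component.
#' @inheritParams cross_validate
#' @return Integer in `0..max_ortho`.
#' @export
select_n_ortho <- function(X, y, max_ortho = 5, k = 7, positive = "AD",
                           min_gain = 0.01, simca_style = FALSE) {
  best <- 0L
  q_prev <- cross_validate(X, y, k = k, n_ortho = 0, positive = positive,
                           simca_style = simca_style)$q2y
  for (j in seq_len(max_ortho)) {
    q_j <- tryCatch(
      cross_validate(X, y, k = k, n_ortho = j, positive = positive,
                     simca_style = simca_style)$q2y,
      error = function(e) -Inf)
    if (q_j - q_prev >= min_gain) {
      best <- j
      q_prev <- q_j
    } else break
  }
  best
}

#' Serialize / restore an OPLS-DA model as JSON
#'
#' Stores weights, loadings, orthogonal components, class coding, the
#' training scaler and metadata in plain JSON so a fitted model can be
#' applied later or elsewhere.
#'
#' @param model An `opls_model`.
#' @param path JSON file path.
#' @return `write_opls` returns `path` invisibly; `read_opls` the restored
#'   `opls_model`.
#' @export
write_opls <- function(model, path) {
  obj <- unclass(model)
  obj$w <- unname(obj$w); obj$p <- unname(obj$p); obj$t <- unname(obj$t)
  obj$coding <- as.list(model$coding)   # keep class names in JSON
  if (!is.null(model$scaler))
    obj$scaler <- list(mean = unname(model$scaler$mean),
                       sd = unname(model$scaler$sd))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor", null = "null")
  invisible(path)
}

#' @rdname write_opls
#' @export
read_opls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$w)
  fix_mat <- function(m) {
    m <- if (is.null(m) || length(m) == 0) matrix(0, p, 0) else as.matrix(m)
    if (nrow(m) != p && length(m)) m <- matrix(unlist(m), nrow = p)
    m
  }
  obj$W_o <- fix_mat(obj$W_o)
  obj$P_o <- fix_mat(obj$P_o)
  obj$T_o <- if (is.null(obj$T_o) || length(obj$T_o) == 0)
    matrix(0, length(obj$t), 0) else as.matrix(obj$T_o)
  obj$coding <- unlist(obj$coding)
  obj$n_ortho <- as.integer(obj$n_ortho)
  names(obj$w) <- names(obj$p) <- obj$features
  if (!is.null(obj$scaler)) {
    obj$scaler <- structure(
      list(mean = stats::setNames(unlist(obj$scaler$mean), obj$features),
           sd = stats::setNames(unlist(obj$scaler$sd), obj$features)),
      class = "uv_scaler")
  }
  structure(obj, class = "opls_model")
}
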