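# Scheltens MTA visual rating: classification and reliability ---------------

#' Age-adjusted abnormality classification of MTA ratings
#'
#' The Scheltens medial-temporal-atrophy scale grades each hemisphere 0 (no
#' atrophy) to 4 (end-stage atrophy) from the width of the choroid fissure
#' and temporal horn and the height of the hippocampus.  A summary of the
#' two sides (their mean by default, or the worse side) is compared with an
#' age-dependent cutoff: a score of 2 or more is abnormal below 75 years,
#' and 3 or more above 75.  Age exactly 75 is not covered by either rule and
#' is assigned the stricter cutoff (3).
#'
#' @param left,right Integer ratings in 0..4 (vectorized).
#' @param age Age in years (>= 0).
#' @param policy `"mean"` to average the sides, `"worst"` to take the
#'   maximum.
#' @return Character vector, `"abnormal"` or `"normal"`.
#' @export
#' @examples
#' classify_mta(2, 2, age = 70)  # abnormal
#' classify_mta(2, 2, age = 80)  # normal
classify_mta <- function(left, right, age, policy = c("mean", "worst")) {
  policy <- match.arg(policy)
  ok <- function(r) all(r %in% 0:4)
  if (!ok(left) || !ok(right)) stop("ratings must be integers in 0..4")
  if (any(age < 0)) stop("'age' must be >= 0")
  score <- if (policy == "mean") (left + right) / 2 else pmax(left, right)
  cutoff <- ifelse(age < 75, 2, 3)
  ifelse(score >= cutoff, "abnormal", "normal")
}

#' Weighted kappa for ordinal agreement
#'
#' Cohen's kappa with linear (default) or quadratic disagreement weights on
#' the fixed 0..4 rating scale, so chance agreement is computed over all
#' five categories even when some are unobserved.
#'
#' @param ratings_a,ratings_b Equal-length integer vectors of ratings.
#' @param weights `"linear"` or `"quadratic"`.
#' @param categories The ordered category set (default 0:4).
#' @return Weighted kappa (1 = perfect agreement, 0 = chance).
#' @export
#' @examples
#' weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3))  # 1
weighted_kappa <- function(ratings_a, ratings_b,
                           weights = c("linear", "quadratic"),
                           categories = 0:4) {
  weights <- match.arg(weights)
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have the same length")
  if (!length(ratings_a)) stop("empty input")
  if (!all(ratings_a %in% categories) || !all(ratings_b %in% categories))
    stop("ratings outside the category set")
  C <- length(categories)
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  O <- table(fa, fb) / length(ratings_a)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(seq_len(C), seq_len(C), `-`)) / (C - 1)
  V <- if (weights == "linear") d else d^2   # disagreement weights
  denom <- sum(V * E)
  if (denom == 0) {
    warning("no chance disagreement; kappa defined as 1")
    return(1)
  }
  1 - sum(V * O) / denom
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the classical mean-squares decomposition of a subjects x repeats table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param measurements Numeric matrix, subjects in rows, repeated
#'   measurements in columns (>= 2 of each).
#' @return The ICC estimate.  A table with no variance at all is degenerate
#'   and returns 1 with a warning.
#' @export
icc_absolute <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 repeats")
  if (anyNA(m)) stop("missing measurements are not supported")
  if (stats::sd(as.vector(m)) == 0) {
    warning("all measurements identical; ICC defined as 1")
    return(1)
  }
  df <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  # only the mean squares are used, so the F-test warnings that perfect
  # fits provoke are irrelevant here
  ms <- suppressWarnings(
    stats::anova(stats::lm(value ~ subject + rater, data = df)))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
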