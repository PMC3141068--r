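# Diagnostic-accuracy arithmetic ---------------------------------------------
#
# 2x2 tables from continuous scores, sensitivity/specificity/accuracy with
# Wilson score intervals, likelihood ratios with log-method intervals, and
# fixed-specificity thresholding.  AD is the positive class throughout and a
# score exactly at the threshold classifies negative (control).

#' Build a confusion table from scores
#'
#' @param true_labels Binary labels; `positive` marks the disease class.
#' @param scores Finite numeric scores, larger = more disease-like.
#' @param threshold Classification cut; scores strictly above it are called
#'   positive, scores at or below it negative.
#' @param positive Positive-class label.
#' @return An object of class `confusion_table` with integer fields `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion(c("AD", "AD", "CTL"), c(1.2, -0.1, -2))
confusion <- function(true_labels, scores, threshold = 0,
                      positive = "AD") {
  true_labels <- as.character(true_labels)
  lev <- unique(true_labels)
  if (length(lev) > 2 || !positive %in% lev)
    stop("labels must be binary with positive class '", positive, "'")
  if (length(true_labels) != length(scores))
    stop("labels and scores must have the same length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- true_labels == positive
  called_pos <- scores > threshold
  structure(list(
    tp = sum(pos & called_pos), fn = sum(pos & !called_pos),
    fp = sum(!pos & called_pos), tn = sum(!pos & !called_pos)
  ), class = "confusion_table")
}

#' Assemble a confusion table directly from its four counts
#'
#' @param tp,fn,fp,tn Non-negative integer cell counts (AD-positive
#'   convention: `tp + fn` diseased, `fp + tn` healthy).
#' @return A `confusion_table`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(lapply(as.list(cells), as.integer), class = "confusion_table")
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param level Confidence level.
#' @return Named vector `c(lower, upper)` in percent.
#' @export
#' @examples
#' round(wilson_ci(59, 75), 1)  # 68.1 86.4
wilson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("'n' must be positive")
  if (successes < 0 || successes > n)
    stop("'successes' must lie in 0..n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  100 * c(lower = (centre - half) / denom, upper = (centre + half) / denom)
}

#' Log-method confidence intervals for likelihood ratios
#'
#' `exp(log(LR) +/- z * SE)` with `SE^2(log LR+) = 1/tp - 1/(tp+fn) + 1/fp -
#' 1/(fp+tn)` and the analogous expression (fn, tn) for LR-.  If a cell
#' entering an SE is zero, 0.5 is added to every cell of that ratio's
#' computation (continuity correction, reported via a message).
#'
#' @param ct A `confusion_table`.
#' @param level Confidence level.
#' @return List with numeric vectors `lr_plus` and `lr_minus`, each
#'   `c(estimate, lower, upper)`.
#' @export
lr_ci <- function(ct, level = 0.95) {
  if (!inherits(ct, "confusion_table")) stop("need a confusion_table")
  z <- stats::qnorm(1 - (1 - level) / 2)
  one <- function(a, b, n1, n0) {
    # LR = (a/n1) / (b/n0); SE on the log scale from the two binomials.
    # The point estimate always uses the raw counts (0 and Inf allowed);
    # a zero cell only triggers a continuity correction for the interval.
    est <- if (b == 0) Inf else (a / n1) / (b / n0)
    if (a == 0 || b == 0) {
      message("zero cell: applying 0.5 continuity correction to the CI")
      a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 1; n0 <- n0 + 1
    }
    lr <- (a / n1) / (b / n0)
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
    c(estimate = est,
      lower = min(est, exp(log(lr) - z * se)),
      upper = max(est, exp(log(lr) + z * se)))
  }
  n1 <- ct$tp + ct$fn
  n0 <- ct$fp + ct$tn
  if (n1 == 0 || n0 == 0) stop("empty class in confusion table")
  list(lr_plus = one(ct$tp, ct$fp, n1, n0),
       lr_minus = one(ct$fn, ct$tn, n1, n0))
}

#' Diagnostic summary of a confusion table
#'
#' Sensitivity, specificity and accuracy in percent with Wilson score
#' intervals, and positive/negative likelihood ratios (`LR+ =
#' sens/(100-spec)`, `LR- = (100-sens)/spec`) with log-method intervals.
#'
#' @param object A `confusion_table`.
#' @param level Confidence level for all intervals.
#' @param ... Unused.
#' @return An object of class `diagnostic_summary`: a list with `counts` and
#'   per-metric `c(estimate, lower, upper)` vectors `sensitivity`,
#'   `specificity`, `accuracy` (percent), `lr_plus`, `lr_minus`.
#' @export
#' @examples
#' summary(confusion_counts(tp = 70, fn = 5, fp = 12, tn = 69))
summary.confusion_table <- function(object, level = 0.95, ...) {
  ct <- object
  n1 <- ct$tp + ct$fn
  n0 <- ct$fp + ct$tn
  if (n1 == 0 || n0 == 0) stop("empty class in confusion table")
  met <- function(k, n) c(estimate = 100 * k / n, wilson_ci(k, n, level))
  sens <- met(ct$tp, n1)
  spec <- met(ct$tn, n0)
  acc <- met(ct$tp + ct$tn, n1 + n0)
  if (ct$fp == 0)
    warning("specificity is 100%: LR+ is infinite")
  lrs <- lr_ci(ct, level)
  structure(list(
    counts = ct, n_pos = n1, n_neg = n0, level = level,
    sensitivity = sens, specificity = spec, accuracy = acc,
    lr_plus = lrs$lr_plus, lr_minus = lrs$lr_minus
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(v, d) sprintf("%.*f (%.*f-%.*f)", d, v[1], d, v[2], d, v[3])
  cat("Diagnostic summary (AD positive; level ",
      format(100 * x$level), "%)\n", sep = "")
  cat("  counts: tp=", x$counts$tp, " fn=", x$counts$fn,
      " fp=", x$counts$fp, " tn=", x$counts$tn, "\n", sep = "")
  cat("  sensitivity:", fmt(x$sensitivity, 1), "%\n")
  cat("  specificity:", fmt(x$specificity, 1), "%\n")
  cat("  accuracy:   ", fmt(x$accuracy, 1), "%\n")
  cat("  LR+:        ", fmt(x$lr_plus, 1), "\n")
  cat("  LR-:        ", fmt(x$lr_minus, 2), "\n")
  invisible(x)
}

#' Smallest threshold achieving a target specificity
#'
#' Sweeps the achievable operating points of a continuous score on the
#' negative (control-like) sample and returns the smallest threshold whose
#' specificity (fraction of negative scores at or below the threshold) is at
#' least the target, together with that achieved specificity.
#'
#' @param negative_scores Scores of the truly negative subjects.
#' @param target_spec Target specificity in percent, in (0, 100].
#' @return List with `threshold` and `specificity` (percent, achieved).
#' @export
threshold_for_specificity <- function(negative_scores, target_spec) {
  if (!length(negative_scores)) stop("no negative scores supplied")
  if (target_spec <= 0 || target_spec > 100)
    stop("'target_spec' must be in (0, 100]")
  s <- sort(negative_scores)
  n <- length(s)
  m <- ceiling(n * target_spec / 100)
  thr <- s[m]
  list(threshold = thr, specificity = 100 * mean(negative_scores <= thr))
}
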