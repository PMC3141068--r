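# Transfer of trained AD/CTL models to MCI conversion prediction ------------

#' Apply a trained AD-vs-control model to MCI subjects
#'
#' MCI subjects play no part in training: their raw features are scaled with
#' the model's stored training scaler and projected through the fitted
#' model unchanged.  A predicted class value above the threshold labels the
#' subject AD-like; at or below it (including exactly at it), CTL-like.
#'
#' @param model An `opls_model` carrying its training scaler.
#' @param X_mci Raw feature matrix of the MCI subjects (same columns as the
#'   training features).
#' @param threshold Classification cut on the coded scale (default 0, the
#'   coded midpoint).
#' @return Character vector, `"AD-like"` or `"CTL-like"`, named by subject.
#' @export
transfer_predict <- function(model, X_mci, threshold = 0) {
  if (!inherits(model, "opls_model")) stop("need an 'opls_model'")
  if (is.null(model$scaler))
    stop("model stores no training scaler; refit with scaler = ...")
  X_mci <- as.matrix(X_mci)
  if (!is.null(rownames(X_mci)) && !is.null(model$train_ids) &&
      any(rownames(X_mci) %in% model$train_ids))
    stop("MCI subjects overlap the model's training set")
  pred <- predict(model, X_mci, raw = TRUE)
  stats::setNames(ifelse(pred > threshold, "AD-like", "CTL-like"),
                  rownames(X_mci))
}

.round_half_up <- function(x) floor(x + 0.5)

#' Tabulate conversion predictions
#'
#' Counts and integer percentages (half-up rounding) of AD-like and
#' CTL-like calls among MCI converters and non-converters.
#'
#' @param labels `"AD-like"`/`"CTL-like"` per MCI subject.
#' @param converter_flags Logical, `TRUE` for subjects who converted to AD.
#' @return A data.frame of class `conversion_summary` with rows
#'   `converters` and `non_converters`: `n`, `ad_like`, `ctl_like`,
#'   `ad_like_pct`, `ctl_like_pct`.
#' @export
#' @examples
#' conversion_table(rep(c("AD-like", "CTL-like"), c(15, 4)),
#'                  rep(TRUE, 19))
conversion_table <- function(labels, converter_flags) {
  if (length(labels) != length(converter_flags))
    stop("labels and converter flags must have the same length")
  if (!all(labels %in% c("AD-like", "CTL-like")))
    stop("labels must be 'AD-like' or 'CTL-like'")
  if (anyNA(converter_flags)) stop("converter flags must not be missing")
  row_for <- function(sel) {
    n <- sum(sel)
    ad <- sum(labels[sel] == "AD-like")
    data.frame(
      n = n, ad_like = ad, ctl_like = n - ad,
      ad_like_pct = if (n) .round_half_up(100 * ad / n) else NA_real_,
      ctl_like_pct = if (n) .round_half_up(100 * (n - ad) / n) else NA_real_
    )
  }
  out <- rbind(converters = row_for(converter_flags),
               non_converters = row_for(!converter_flags))
  class(out) <- c("conversion_summary", "data.frame")
  out
}

#' Compare methods at a fixed specificity
#'
#' The visual rating has no tunable threshold, so its specificity on stable
#' MCI (fraction called CTL-like) anchors the comparison: every
#' continuous-score method is re-thresholded on the stable-MCI scores to
#' the smallest threshold meeting that specificity from above, and
#' converter sensitivity is recomputed there.  The anchor method keeps its
#' original operating point (fixed point of the procedure).
#'
#' @param method_scores Named list of numeric score vectors (one per
#'   continuous method), aligned with `converter_flags`; larger = more
#'   AD-like.
#' @param reference_labels `"AD-like"`/`"CTL-like"` calls of the anchor
#'   method, aligned with `converter_flags`.
#' @param converter_flags Logical conversion flags for the same subjects.
#' @param reference_name Row name for the anchor method.
#' @return A data.frame: per method, `target_specificity`,
#'   `achieved_specificity`, `sensitivity` (percent) and `threshold` (NA
#'   for the anchor).
#' @export
fixed_specificity_compare <- function(method_scores, reference_labels,
                                      converter_flags,
                                      reference_name = "visual") {
  if (!length(method_scores) || is.null(names(method_scores)))
    stop("'method_scores' must be a named list")
  stable <- !converter_flags
  if (!any(stable)) stop("no stable-MCI subjects to anchor specificity")
  target <- 100 * mean(reference_labels[stable] == "CTL-like")
  if (target <= 0)
    stop("anchor specificity is 0%; no attainable target")
  rows <- lapply(names(method_scores), function(nm) {
    sc <- method_scores[[nm]]
    if (length(sc) != length(converter_flags))
      stop("scores for '", nm, "' do not align with converter flags")
    op <- threshold_for_specificity(sc[stable], target)
    data.frame(
      method = nm, target_specificity = target,
      achieved_specificity = op$specificity,
      sensitivity = 100 * mean(sc[converter_flags] > op$threshold),
      threshold = op$threshold, stringsAsFactors = FALSE
    )
  })
  ref <- data.frame(
    method = reference_name, target_specificity = target,
    achieved_specificity = target,
    sensitivity = 100 * mean(reference_labels[converter_flags] == "AD-like"),
    threshold = NA_real_, stringsAsFactors = FALSE
  )
  out <- rbind(ref, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
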