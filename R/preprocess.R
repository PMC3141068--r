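# Feature assembly and scaling ----------------------------------------------

#' Normalize a volume by intracranial volume
#'
#' @param volume Volume in mm^3 (vectorized).
#' @param icv Intracranial volume in mm^3; must be positive.
#' @return Dimensionless ratio `volume / icv`.
#' @export
normalize_by_icv <- function(volume, icv) {
  if (any(!is.finite(icv)) || any(icv <= 0))
    stop("'icv' must be positive and finite")
  volume / icv
}

#' Average left and right hemisphere measures
#'
#' No imputation: a missing side is an error.
#'
#' @param left,right Numeric vectors of equal length.
#' @return Element-wise arithmetic mean.
#' @export
average_bilateral <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right must have the same length")
  if (any(is.na(left)) || any(is.na(right)))
    stop("missing hemisphere measure; no imputation is performed")
  (left + right) / 2
}

#' Assemble the 57-variable analysis matrix
#'
#' Builds the subjects x 57 feature matrix from a cohort table: the 34
#' regional cortical thicknesses (mm) and the 23 regional volumes, each
#' volume normalized by the subject's intracranial volume per hemisphere and
#' then bilaterally averaged (the ratio is linear in the volume, so
#' normalizing before or after averaging is equivalent).  Thickness is never
#' ICV-normalized.  Column order is fixed: thickness features
#' (`thk_<region>`) then volume features (`vol_<region>`), matching
#' [atrophy_effect_template()].
#'
#' @param cohort An `mtl_cohort` data.frame (or any data.frame with the same
#'   column dictionary).
#' @return Numeric matrix, rows named by `subject_id`, 57 named columns.
#' @export
assemble_features <- function(cohort) {
  rg <- mtl_regions()
  thk <- vapply(rg$thickness, function(r)
    average_bilateral(cohort[[paste0("thk_left_", r)]],
                      cohort[[paste0("thk_right_", r)]]),
    numeric(nrow(cohort)))
  vol <- vapply(rg$volume, function(r)
    average_bilateral(
      normalize_by_icv(cohort[[paste0("vol_left_", r)]], cohort$icv),
      normalize_by_icv(cohort[[paste0("vol_right_", r)]], cohort$icv)),
    numeric(nrow(cohort)))
  X <- cbind(thk, vol)
  colnames(X) <- c(paste0("thk_", rg$thickness), paste0("vol_", rg$volume))
  rownames(X) <- cohort$subject_id
  if (anyNA(X)) stop("assembled feature matrix contains missing values")
  X
}

#' Total manually outlined hippocampal volume, ICV-normalized
#'
#' The single-predictor feature used by the manual-outlining classifier:
#' left + right manual hippocampal volume divided by intracranial volume.
#'
#' @param cohort An `mtl_cohort` data.frame.
#' @return One-column matrix `manual_hippocampus_total`, rows named by
#'   subject.
#' @export
assemble_manual_hippo <- function(cohort) {
  tot <- normalize_by_icv(cohort$manual_hippo_left + cohort$manual_hippo_right,
                          cohort$icv)
  matrix(tot, ncol = 1,
         dimnames = list(cohort$subject_id, "manual_hippocampus_total"))
}

#' Mean-centring and unit-variance scaling
#'
#' `fit_scaler` learns per-feature training means and standard deviations
#' (n - 1 denominator); `apply_scaler` centres by the training mean and
#' multiplies by the inverse training SD, or inverts that map.  Applying to
#' new data reuses the training parameters unchanged, so held-out subjects
#' are scaled without leakage.
#'
#' @param X Numeric matrix (subjects x features) with named columns.
#' @return `fit_scaler`: an object of class `uv_scaler` holding `mean` and
#'   `sd` per feature.  `apply_scaler`: the transformed matrix.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 subjects to fit a scaler")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd <= 0 | !is.finite(sd))) {
    bad <- colnames(X)[sd <= 0 | !is.finite(sd)]
    stop("constant feature(s): ", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sd), class = "uv_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `uv_scaler`.
#' @param inverse If `TRUE`, undo the scaling instead.
#' @export
apply_scaler <- function(X, scaler, inverse = FALSE) {
  X <- as.matrix(X)
  if (!inherits(scaler, "uv_scaler")) stop("'scaler' must be a uv_scaler")
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), names(scaler$mean)))
    stop("feature names do not match the scaler's training features")
  if (inverse)
    sweep(sweep(X, 2, scaler$sd, `*`), 2, scaler$mean, `+`)
  else
    sweep(sweep(X, 2, scaler$mean, `-`), 2, scaler$sd, `/`)
}
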