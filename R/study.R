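# End-to-end study replica ---------------------------------------------------
#
# generate cohort -> assemble features -> three classifiers (OPLS on 57
# regional measures, OPLS on total manual hippocampal volume, MTA visual
# rule) -> cross-validated diagnostics -> loading inference -> MCI transfer.

#' Configure a study run
#'
#' Validates the full configuration before any computation.  All randomness
#' in a run flows from `cohort$seed` (cohort draw) and `fold_seed` (fold
#' shuffling; `NULL` keeps the deterministic class-interleaved folds).
#'
#' @param cohort A [cohort_spec()].
#' @param n_ortho Orthogonal components for the 57-feature model, or
#'   `"auto"` to pick via [select_n_ortho()].
#' @param folds Cross-validation folds (default 7).
#' @param ci_level Confidence level for all intervals.
#' @param rating_policy Bilateral MTA combination, `"mean"` or `"worst"`.
#' @param simca_style Scale the full matrix once instead of per training
#'   fold.
#' @param fold_seed Optional seed for shuffled fold assignment.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), n_ortho = 0, folds = 7,
                       ci_level = 0.95, rating_policy = c("mean", "worst"),
                       simca_style = FALSE, fold_seed = NULL) {
  if (!inherits(cohort, "cohort_spec")) stop("'cohort' must be a cohort_spec")
  if (!identical(n_ortho, "auto") &&
      (!is.numeric(n_ortho) || n_ortho < 0 || n_ortho != round(n_ortho)))
    stop("'n_ortho' must be \"auto\" or a non-negative integer")
  if (folds < 2) stop("'folds' must be >= 2")
  if (ci_level <= 0 || ci_level >= 1) stop("'ci_level' must be in (0, 1)")
  rating_policy <- match.arg(rating_policy)
  structure(list(cohort = cohort, n_ortho = n_ortho,
                 folds = as.integer(folds), ci_level = ci_level,
                 rating_policy = rating_policy,
                 simca_style = isTRUE(simca_style), fold_seed = fold_seed),
            class = "run_config")
}

.summary_row <- function(method, ds) {
  data.frame(
    method = method,
    sensitivity = ds$sensitivity[["estimate"]],
    sens_lo = ds$sensitivity[["lower"]], sens_hi = ds$sensitivity[["upper"]],
    specificity = ds$specificity[["estimate"]],
    spec_lo = ds$specificity[["lower"]], spec_hi = ds$specificity[["upper"]],
    accuracy = ds$accuracy[["estimate"]],
    acc_lo = ds$accuracy[["lower"]], acc_hi = ds$accuracy[["upper"]],
    lr_plus = ds$lr_plus[["estimate"]],
    lrp_lo = ds$lr_plus[["lower"]], lrp_hi = ds$lr_plus[["upper"]],
    lr_minus = ds$lr_minus[["estimate"]],
    lrm_lo = ds$lr_minus[["lower"]], lrm_hi = ds$lr_minus[["upper"]],
    stringsAsFactors = FALSE
  )
}

#' Run the full three-method study on a synthetic cohort
#'
#' Generates a cohort, trains the two OPLS-DA classifiers on AD and control
#' subjects only (57 regional measures; single total manual hippocampal
#' volume), evaluates all three methods (including the age-adjusted MTA
#' visual rule) with cross-validated predictions, computes covariance
#' loadings with jack-knifed reliability flags, and transfers the trained
#' models untouched to the MCI subjects, including the fixed-specificity
#' comparison anchored on the visual rating.
#'
#' @param config A [run_config()].
#' @return An object of class `mtl_study`: `config`, `cohort`, `models`
#'   (fitted OPLS models), `cv` (cross-validation results), `quality`
#'   (R2X/Q2Y per OPLS model), `table_ad_ctl` (per-method diagnostic
#'   metrics with CIs), `loadings` (inference table for the 57-feature
#'   model), `scores` (per-subject cross-validated predicted values),
#'   `mci` (conversion summaries per method), `fixed_spec` (recalibrated
#'   comparison).
#' @export
run_study <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  cohort <- generate_cohort(config$cohort)
  train <- cohort$group %in% c("AD", "CTL")
  mci <- cohort$group == "MCI"
  if (sum(cohort$group == "AD") == 0 || sum(cohort$group == "CTL") == 0)
    stop("stage training-data: cohort lacks an AD or CTL group")

  X_all <- assemble_features(cohort)
  H_all <- assemble_manual_hippo(cohort)
  X <- X_all[train, , drop = FALSE]
  H <- H_all[train, , drop = FALSE]
  y <- cohort$group[train]

  n_ortho <- config$n_ortho
  if (identical(n_ortho, "auto"))
    n_ortho <- select_n_ortho(X, y, k = config$folds,
                              simca_style = config$simca_style)

  cv_reg <- cross_validate(X, y, k = config$folds, n_ortho = n_ortho,
                           simca_style = config$simca_style,
                           shuffle_seed = config$fold_seed)
  cv_hip <- cross_validate(H, y, k = config$folds, n_ortho = 0,
                           simca_style = config$simca_style,
                           shuffle_seed = config$fold_seed)

  mta_call <- classify_mta(cohort$mta_left, cohort$mta_right, cohort$age,
                           policy = config$rating_policy)
  # visual rule as a score on the coded scale: abnormal -> +1, normal -> -1
  mta_score <- ifelse(mta_call == "abnormal", 1, -1)

  ds <- list(
    regional_opls = summary(confusion(y, cv_reg$y_pred),
                            level = config$ci_level),
    visual_rating = summary(confusion(y, mta_score[train]),
                            level = config$ci_level),
    manual_hippocampus = summary(confusion(y, cv_hip$y_pred),
                                 level = config$ci_level)
  )
  table_ad_ctl <- do.call(rbind, Map(.summary_row, names(ds), ds))
  rownames(table_ad_ctl) <- NULL

  loadings <- jackknife_intervals(cv_reg, level = config$ci_level)

  # MCI transfer: trained models applied untouched
  conv <- cohort$converter[mci]
  mci_scores <- list(
    regional_opls = predict(cv_reg$full_model,
                            X_all[mci, , drop = FALSE], raw = TRUE),
    manual_hippocampus = predict(cv_hip$full_model,
                                 H_all[mci, , drop = FALSE], raw = TRUE)
  )
  mci_labels <- c(
    list(visual_rating = ifelse(mta_call[mci] == "abnormal",
                                "AD-like", "CTL-like")),
    lapply(mci_scores, function(s) ifelse(s > 0, "AD-like", "CTL-like"))
  )
  mci_tables <- lapply(mci_labels, conversion_table, converter_flags = conv)
  fixed_spec <- fixed_specificity_compare(
    mci_scores, reference_labels = mci_labels$visual_rating,
    converter_flags = conv, reference_name = "visual_rating")

  scores <- data.frame(
    subject_id = cohort$subject_id[train], group = y,
    fold = cv_reg$fold, regional_opls = cv_reg$y_pred,
    manual_hippocampus = cv_hip$y_pred, stringsAsFactors = FALSE
  )

  structure(list(
    config = config, cohort = cohort,
    models = list(regional_opls = cv_reg$full_model,
                  manual_hippocampus = cv_hip$full_model),
    cv = list(regional_opls = cv_reg, manual_hippocampus = cv_hip),
    quality = data.frame(
      model = c("regional_opls", "manual_hippocampus"),
      n_ortho = c(n_ortho, 0L),
      R2X = c(cv_reg$full_model$R2X, cv_hip$full_model$R2X),
      Q2Y = c(cv_reg$q2y, cv_hip$q2y), stringsAsFactors = FALSE
    ),
    table_ad_ctl = table_ad_ctl, loadings = loadings, scores = scores,
    mci = mci_tables, fixed_spec = fixed_spec
  ), class = "mtl_study")
}

#' @export
print.mtl_study <- function(x, ...) {
  cat("Three-method AD/CTL discrimination study (synthetic cohort)\n")
  cat(sprintf("  subjects: %d AD, %d CTL, %d MCI (%d converters)\n",
              sum(x$cohort$group == "AD"), sum(x$cohort$group == "CTL"),
              sum(x$cohort$group == "MCI"),
              sum(x$cohort$converter %in% TRUE)))
  cat("\nModel quality:\n")
  print(transform(x$quality, R2X = round(R2X, 3), Q2Y = round(Q2Y, 3)),
        row.names = FALSE)
  cat("\nAD vs CTL diagnostics (percent, 95% CI):\n")
  t3 <- x$table_ad_ctl
  for (i in seq_len(nrow(t3))) {
    cat(sprintf(
      "  %-20s sens %.1f (%.1f-%.1f)  spec %.1f (%.1f-%.1f)  acc %.1f (%.1f-%.1f)  LR+ %.1f  LR- %.2f\n",
      t3$method[i], t3$sensitivity[i], t3$sens_lo[i], t3$sens_hi[i],
      t3$specificity[i], t3$spec_lo[i], t3$spec_hi[i],
      t3$accuracy[i], t3$acc_lo[i], t3$acc_hi[i],
      t3$lr_plus[i], t3$lr_minus[i]))
  }
  cat(sprintf("\nReliable loadings: %d of %d features\n",
              sum(x$loadings$reliable), nrow(x$loadings)))
  cat("\nMCI conversion (percent AD-like among converters / CTL-like among stable):\n")
  for (nm in names(x$mci)) {
    tb <- x$mci[[nm]]
    cat(sprintf("  %-20s converters %d%% (%d/%d)   stable CTL-like %d%% (%d/%d)\n",
                nm, tb["converters", "ad_like_pct"],
                tb["converters", "ad_like"], tb["converters", "n"],
                tb["non_converters", "ctl_like_pct"],
                tb["non_converters", "ctl_like"], tb["non_converters", "n"]))
  }
  invisible(x)
}

#' Write the study report bundle
#'
#' Emits plain-text artefacts for a run: the AD/CTL diagnostic table, the
#' MCI conversion tables, the fixed-specificity comparison, the loading
#' inference table, the per-subject cross-validated scores (score-plot
#' data) and a JSON provenance record of the full configuration.  Identical
#' config and seed produce byte-identical files.
#'
#' @param study An `mtl_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "mtl_study")) stop("need an 'mtl_study'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(study$table_ad_ctl, "ad_ctl_diagnostics.csv")
  wr(study$loadings, "loading_inference.csv")
  wr(study$scores, "cv_scores.csv")
  wr(study$fixed_spec, "mci_fixed_specificity.csv")
  mci <- do.call(rbind, lapply(names(study$mci), function(nm)
    cbind(method = nm, status = rownames(study$mci[[nm]]),
          study$mci[[nm]], stringsAsFactors = FALSE)))
  wr(mci, "mci_conversion.csv")
  wr(study$quality, "model_quality.csv")
  cfg <- study$config
  jsonlite::write_json(
    list(cohort = unclass(cfg$cohort), n_ortho = cfg$n_ortho,
         folds = cfg$folds, ci_level = cfg$ci_level,
         rating_policy = cfg$rating_policy, simca_style = cfg$simca_style,
         fold_seed = cfg$fold_seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
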