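# Synthetic cohort generation ------------------------------------------------
#
# Emulates the per-subject tables of a multicentre AD imaging study: 34
# regional cortical thicknesses and 23 regional volumes per hemisphere,
# intracranial volume, manually outlined hippocampal volume, Scheltens MTA
# visual ratings, and an MCI one-year conversion flag.

#' Region names for the regional MRI feature set
#'
#' 34 cortical parcellation units carrying thickness measures and 23
#' segmentation structures carrying volume measures.  These fix the column
#' dictionary of generated cohorts and the ordering of the 57-variable
#' analysis matrix (thickness features first, then volume features).
#'
#' @return A list with character vectors `thickness` (length 34) and
#'   `volume` (length 23).
#' @export
#' @examples
#' lengths(mtl_regions())
mtl_regions <- function() {
  list(
    thickness = c(
      "entorhinal", "parahippocampal", "temporalpole", "fusiform",
      "inferiortemporal", "middletemporal", "superiortemporal", "bankssts",
      "isthmuscingulate", "inferiorparietal", "supramarginal", "precuneus",
      "posteriorcingulate", "caudalanteriorcingulate", "caudalmiddlefrontal",
      "cuneus", "frontalpole", "insula", "lateraloccipital",
      "lateralorbitofrontal", "lingual", "medialorbitofrontal", "paracentral",
      "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
      "postcentral", "precentral", "rostralanteriorcingulate",
      "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
      "transversetemporal"
    ),
    volume = c(
      "hippocampus", "amygdala", "accumbens_area", "thalamus",
      "lateral_ventricle", "inferior_lateral_ventricle", "third_ventricle",
      "csf", "choroid_plexus", "white_matter_hypointensities", "cortex",
      "cerebral_white_matter", "caudate", "putamen", "pallidum", "ventral_dc",
      "cerebellum_cortex", "cerebellum_white_matter", "fourth_ventricle",
      "optic_chiasm", "corpus_callosum", "brainstem", "vessel"
    )
  )
}

#' Canonical atrophy effect template
#'
#' Signed standardized group-difference pattern (AD relative to control) for
#' the 57 analysis features.  Medial temporal structures (hippocampus,
#' amygdala, entorhinal and neighbouring temporal-lobe cortex) atrophy, so
#' their sign is -1; CSF spaces (ventricles, choroid fissure region) enlarge,
#' so their sign is +1; regions largely spared early in AD have effect 0.
#' The magnitude column is in Cohen's d units per unit `effect_scale` of the
#' cohort specification.
#'
#' @return A data.frame with one row per feature: `feature`, `block`
#'   (`"thickness"` or `"volume"`), `sign` (-1, 0, +1) and `magnitude`
#'   (non-negative).  Deterministic.
#' @export
#' @examples
#' tpl <- atrophy_effect_template()
#' subset(tpl, feature == "vol_hippocampus")$sign      # -1 (atrophy)
#' subset(tpl, feature == "vol_lateral_ventricle")$sign  # +1 (CSF expansion)
atrophy_effect_template <- function() {
  rg <- mtl_regions()
  thick_mag <- c(
    entorhinal = 1.0, parahippocampal = 0.8, temporalpole = 0.8,
    fusiform = 0.6, inferiortemporal = 0.7, middletemporal = 0.7,
    superiortemporal = 0.6, bankssts = 0.4, isthmuscingulate = 0.4,
    inferiorparietal = 0.5, supramarginal = 0.4, precuneus = 0.4,
    posteriorcingulate = 0.3
  )
  vol_eff <- c(
    hippocampus = -1.0, amygdala = -0.9, accumbens_area = -0.4,
    thalamus = -0.3, lateral_ventricle = 0.9,
    inferior_lateral_ventricle = 1.0, third_ventricle = 0.6, csf = 0.5,
    choroid_plexus = 0.3, white_matter_hypointensities = 0.3,
    cortex = -0.5, cerebral_white_matter = -0.3
  )
  t_mag <- ifelse(rg$thickness %in% names(thick_mag),
                  thick_mag[rg$thickness], 0)
  t_mag[is.na(t_mag)] <- 0
  v_sig <- ifelse(rg$volume %in% names(vol_eff), vol_eff[rg$volume], 0)
  v_sig[is.na(v_sig)] <- 0
  data.frame(
    feature = c(paste0("thk_", rg$thickness), paste0("vol_", rg$volume)),
    block = rep(c("thickness", "volume"), c(34L, 23L)),
    sign = c(-as.numeric(t_mag > 0), sign(v_sig)),
    magnitude = c(as.numeric(t_mag), abs(v_sig)),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic cohort
#'
#' Collects and validates the knobs of the cohort generator.  Defaults mirror
#' the group sizes of the emulated study (75 AD, 81 controls, 101 MCI of whom
#' 19 converted to AD within one year).
#'
#' @param n_ad,n_ctl,n_mci_conv,n_mci_stable Group sizes (non-negative
#'   integers).
#' @param effect_scale Multiplier on the atrophy template, in Cohen's d units
#'   per unit template magnitude.  0 means no group separation.
#' @param noise_sd Within-group standard deviation of each (bilaterally
#'   averaged) feature on the standardized latent scale.
#' @param rating_noise_sd Standard deviation of the per-side rater noise
#'   added to the latent atrophy score before discretization into MTA grades.
#' @param mci_stable_ctl_weight Probability that a stable-MCI subject is
#'   drawn from the control-like component of the stable mixture.
#' @param hippo_manual_r Correlation between the manually outlined
#'   hippocampal volume and the automated hippocampal volume feature.
#' @param block_rho Exchangeable correlation within the template-active and
#'   within the template-null subsets of each feature block.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_ad = 75L, n_ctl = 81L, n_mci_conv = 19L,
                        n_mci_stable = 82L, effect_scale = 1.5,
                        noise_sd = 1, rating_noise_sd = 0.3,
                        mci_stable_ctl_weight = 0.7, hippo_manual_r = 0.9,
                        block_rho = 0.3, seed = 1L) {
  counts <- c(n_ad = n_ad, n_ctl = n_ctl, n_mci_conv = n_mci_conv,
              n_mci_stable = n_mci_stable)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("group sizes must be non-negative integers")
  if (effect_scale < 0) stop("'effect_scale' must be >= 0")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (rating_noise_sd < 0) stop("'rating_noise_sd' must be >= 0")
  if (mci_stable_ctl_weight < 0 || mci_stable_ctl_weight > 1)
    stop("'mci_stable_ctl_weight' must be in [0, 1]")
  if (abs(hippo_manual_r) > 1) stop("'hippo_manual_r' must be in [-1, 1]")
  if (block_rho < 0 || block_rho >= 1) stop("'block_rho' must be in [0, 1)")
  structure(list(
    n_ad = as.integer(n_ad), n_ctl = as.integer(n_ctl),
    n_mci_conv = as.integer(n_mci_conv),
    n_mci_stable = as.integer(n_mci_stable),
    effect_scale = effect_scale, noise_sd = noise_sd,
    rating_noise_sd = rating_noise_sd,
    mci_stable_ctl_weight = mci_stable_ctl_weight,
    hippo_manual_r = hippo_manual_r, block_rho = block_rho,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Fraction of the marginal feature variance contributed by independent
# per-hemisphere measurement noise (before bilateral averaging).  The core
# (subject-level) draw is deconvolved so that the bilaterally averaged
# feature has SD exactly `noise_sd`.
.side_noise_frac <- 0.2

# Ordinal cut points on the latent medial-temporal atrophy scale (in
# control-group SD units) mapping to MTA grades 1, 2, 3, 4.  Chosen so that
# controls mostly rate 0-1 and a typical AD subject rates 2-4, giving the
# visual rule a clinically plausible operating point under the default
# effect scale.
.mta_cuts <- c(0.4, 1.1, 2.1, 3.1)

# Features entering the latent atrophy score that drives MTA ratings and is
# mirrored by the manual hippocampal outline.
.mtl_latent_features <- c("vol_hippocampus", "vol_amygdala",
                          "thk_entorhinal", "thk_parahippocampal")

# Control-group SD of the (negated) mean of the four latent MTL features,
# in noise_sd units: the four features are pairwise correlated block_rho
# (attenuated by the per-side noise share) within their block, with the
# two blocks independent.
.mtl_latent_sd <- function(block_rho) {
  rho_eff <- block_rho * (1 - .side_noise_frac^2 / 2)
  sqrt((4 + 4 * rho_eff) / 16)
}

# Correlation matrix of the 57 latent features: exchangeable block_rho within
# the template-active and within the template-null subset of each block.
# Keeping the two subsets uncorrelated makes template-null features carry no
# class information at all (their covariance loadings are truly zero), while
# the correlated null subset supplies genuine y-orthogonal structure.
.latent_correlation <- function(block_rho) {
  tpl <- atrophy_effect_template()
  R <- diag(57)
  for (blk in c("thickness", "volume")) {
    for (active in c(TRUE, FALSE)) {
      idx <- which(tpl$block == blk & (tpl$sign != 0) == active)
      if (length(idx) > 1) R[idx, idx] <- block_rho + diag(1 - block_rho,
                                                           length(idx))
    }
  }
  R
}

#' Discretize latent medial-temporal atrophy into MTA ratings
#'
#' Each hemisphere's rating is the shared latent atrophy score plus
#' independent per-side rater noise, cut at four fixed ordered thresholds
#' into grades 0 (no atrophy) to 4 (end-stage atrophy).
#'
#' @param latent_atrophy Numeric vector of standardized latent atrophy
#'   scores (higher = more atrophy).
#' @param rating_noise_sd Non-negative SD of the per-side rater noise.
#' @param seed Optional integer seed (set only when supplied, so the
#'   function can also run inside an existing RNG stream).
#' @return Integer matrix with columns `left` and `right`, entries in 0..4.
#' @export
#' @examples
#' generate_ratings(c(-2, 0.7, 3.5), rating_noise_sd = 0)
generate_ratings <- function(latent_atrophy, rating_noise_sd = 0.3,
                             seed = NULL) {
  if (rating_noise_sd < 0) stop("'rating_noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(latent_atrophy)
  one_side <- function() {
    obs <- latent_atrophy + stats::rnorm(n, sd = rating_noise_sd)
    findInterval(obs, .mta_cuts)
  }
  cbind(left = one_side(), right = one_side())
}

#' Generate a synthetic AD/MCI/control cohort
#'
#' Draws per-subject records with the statistical structure the downstream
#' analysis assumes: a 57-dimensional latent feature vector per subject with
#' group means shifted along the atrophy template, correlated within blocks,
#' observed per hemisphere with independent measurement noise and mapped to
#' raw units (mm for thickness, ICV-proportional mm^3 for volumes); a manual
#' hippocampal outline correlated with the automated hippocampal feature;
#' and Scheltens MTA ratings discretized from the latent medial-temporal
#' atrophy score.  MCI converters are drawn from the AD distribution; stable
#' MCI from a control/AD mixture.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of class `mtl_cohort`, one row per subject, with the
#'   spec attached as attribute `"spec"`.  Columns: `subject_id`, `group`
#'   (`AD`/`CTL`/`MCI`), `converter` (logical, `NA` outside MCI), `age`
#'   (years), `icv` (mm^3), `thk_left_*`/`thk_right_*` (mm, 34 regions each),
#'   `vol_left_*`/`vol_right_*` (mm^3, 23 regions each),
#'   `manual_hippo_left`/`manual_hippo_right` (mm^3), `mta_left`/`mta_right`
#'   (0-4).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_ad = 5, n_ctl = 5, n_mci_conv = 2,
#'                                    n_mci_stable = 3, seed = 7))
#' table(coh$group)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  set.seed(spec$seed)
  tpl <- atrophy_effect_template()
  p <- nrow(tpl)
  n <- spec$n_ad + spec$n_ctl + spec$n_mci_conv + spec$n_mci_stable
  group <- rep(c("AD", "CTL", "MCI"),
               c(spec$n_ad, spec$n_ctl, spec$n_mci_conv + spec$n_mci_stable))
  converter <- rep(NA, n)
  converter[group == "MCI"] <- rep(c(TRUE, FALSE),
                                   c(spec$n_mci_conv, spec$n_mci_stable))

  # which subjects carry the AD mean shift
  stable_idx <- which(group == "MCI" & !converter)
  ad_like <- group == "AD" | (group == "MCI" & converter %in% TRUE)
  if (length(stable_idx))
    ad_like[stable_idx] <- stats::runif(length(stable_idx)) >
      spec$mci_stable_ctl_weight

  delta <- spec$effect_scale * tpl$sign * tpl$magnitude * spec$noise_sd
  side_sd <- .side_noise_frac * spec$noise_sd
  core_var <- spec$noise_sd^2 - side_sd^2 / 2
  Sigma <- core_var * .latent_correlation(spec$block_rho)
  core <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
  core[ad_like, ] <- sweep(core[ad_like, , drop = FALSE], 2, delta, `+`)
  z_left <- core + matrix(stats::rnorm(n * p, sd = side_sd), n)
  z_right <- core + matrix(stats::rnorm(n * p, sd = side_sd), n)

  age <- stats::runif(n, 65, 85)
  icv <- stats::rnorm(n, 1.45e6, 1.2e5)
  icv_ratio <- icv / 1.45e6

  rg <- mtl_regions()
  vol_base <- .volume_base_mm3()[rg$volume]
  t_idx <- seq_len(34)
  v_idx <- 34L + seq_len(23L)
  to_raw <- function(z) {
    thk <- 2.5 + 0.25 * z[, t_idx, drop = FALSE]
    vol <- sweep(z[, v_idx, drop = FALSE] * 0.12 + 1, 2, vol_base, `*`) *
      icv_ratio
    vol <- pmax(vol, 0)
    list(thk = thk, vol = vol)
  }
  L <- to_raw(z_left)
  R <- to_raw(z_right)

  # manual hippocampal outline: attenuated copy of each side's automated
  # hippocampal feature plus independent tracing error, on the same
  # ICV-proportional raw scale
  r <- spec$hippo_manual_r
  hip <- which(tpl$feature == "vol_hippocampus")
  manual_z <- function(zside) {
    r * zside[, hip] +
      sqrt(max(0, 1 - r^2)) * stats::rnorm(n, sd = spec$noise_sd)
  }
  manual_raw <- function(mz) pmax(3400 * (1 + 0.12 * mz) * icv_ratio, 0)
  manual_left <- manual_raw(manual_z(z_left))
  manual_right <- manual_raw(manual_z(z_right))

  z_avg <- (z_left + z_right) / 2
  latent <- -rowMeans(z_avg[, match(.mtl_latent_features, tpl$feature),
                            drop = FALSE]) /
    (spec$noise_sd * .mtl_latent_sd(spec$block_rho))
  mta <- generate_ratings(latent, spec$rating_noise_sd)

  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group, converter = converter, age = age, icv = icv,
    stringsAsFactors = FALSE
  )
  add_block <- function(df, prefix, m, regions) {
    colnames(m) <- paste0(prefix, regions)
    cbind(df, as.data.frame(m))
  }
  out <- add_block(out, "thk_left_", L$thk, rg$thickness)
  out <- add_block(out, "thk_right_", R$thk, rg$thickness)
  out <- add_block(out, "vol_left_", L$vol, rg$volume)
  out <- add_block(out, "vol_right_", R$vol, rg$volume)
  out$manual_hippo_left <- manual_left
  out$manual_hippo_right <- manual_right
  out$mta_left <- mta[, "left"]
  out$mta_right <- mta[, "right"]
  attr(out, "spec") <- spec
  class(out) <- c("mtl_cohort", "data.frame")
  out
}

# Typical structure volumes (mm^3) used as raw-scale anchors; any linear
# map per feature is equivalent downstream because of unit-variance scaling.
.volume_base_mm3 <- function() {
  c(hippocampus = 3500, amygdala = 1300, accumbens_area = 500,
    thalamus = 6500, lateral_ventricle = 12000,
    inferior_lateral_ventricle = 600, third_ventricle = 1200, csf = 1000,
    choroid_plexus = 700, white_matter_hypointensities = 1500,
    cortex = 220000, cerebral_white_matter = 230000, caudate = 3400,
    putamen = 4500, pallidum = 1600, ventral_dc = 3800,
    cerebellum_cortex = 50000, cerebellum_white_matter = 14000,
    fourth_ventricle = 1700, optic_chiasm = 200, corpus_callosum = 3000,
    brainstem = 20000, vessel = 50)
}

#' Write / read a cohort as CSV with a JSON sidecar
#'
#' The CSV holds one row per subject with the column dictionary documented
#' in [generate_cohort()]; the sidecar (`<path>.json`) records the
#' generating specification and seed for provenance.
#'
#' @param cohort An `mtl_cohort` data.frame.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `mtl_cohort` data.frame (with the spec re-attached when the sidecar is
#'   present).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$converter <- as.logical(out$converter)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sp <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "spec") <- do.call(cohort_spec, sp)
  }
  class(out) <- c("mtl_cohort", "data.frame")
  out
}
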