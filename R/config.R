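#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' generator in the synthetic-data module.  Defaults reproduce the study
#' conditions the package is calibrated against: a cohort of 348 older
#' men (age mean 65.2, SD 7.9 years), 90.5% white/non-Hispanic, 51.7%
#' hypertensive, 15.5% diabetic, 12.4% population-based controls, an
#' eight-item engagement scale driven by one latent factor with SD 0.33,
#' and the 20-region volume inventory of [roi_inventory()].
#'
#' @param n_subjects Number of subjects to simulate.
#' @param seed Integer root RNG seed.  Each generated object draws from a
#'   deterministic substream of this seed, so regenerating one object does
#'   not shift the others.
#' @param covariate_margins Named list of marginal targets: `age_mean`,
#'   `age_sd` (years), `p_minority`, `p_hypertension`, `p_diabetes`,
#'   `p_control`, `p_nonright` (proportions), `edu_probs` (length-5
#'   probability vector in [education_levels()] order).
#' @param icv_mean,icv_sd Intracranial volume mean and SD in cc.
#' @param engagement_sd SD of the latent engagement score (score units).
#' @param item_loadings Eight factor loadings in \[0, 1\] for the ordinal
#'   items of [engagement_items()].
#' @param item_missing_rate Probability that any single item response is
#'   missing (injected completely at random).
#' @param roi_effects Named numeric vector of standardized engagement
#'   effects (dimensionless, effect per SD of engagement in units of the
#'   region's SD); names must be a subset of `roi_inventory()$roi`.
#'   Unnamed regions default to 0.
#' @param roi_cv Coefficient of variation of region volumes (marginal SD
#'   as a fraction of the mean).
#' @param roi_covariate_coupling Multiplier on the covariate-to-volume
#'   couplings (age slope, hypertension/diabetes/control offsets, ICV
#'   term).  1 = defaults, 0 = volumes depend only on engagement and
#'   noise.
#' @param voxel_covariate_coupling Multiplier on the covariate-driven
#'   global scaling of the voxel maps (ICV and age terms); 0 disables
#'   subject-level scaling.
#' @param delta_mean_frac,delta_sd_frac Mean and SD of the simulated
#'   five-year volume change, as fractions of the region mean (negative
#'   mean = atrophy).
#' @param delta_engagement_coupling Standardized coupling between the
#'   five-year change and engagement (default 0: change is independent of
#'   engagement, the null temporal-reversal condition).
#' @param blob_spec List of effect blobs to embed in the voxel maps; each
#'   element is a list with `center` (voxel triple, 1-based), `radius`
#'   (voxels), `amplitude` (map units per SD of engagement) and `tissue`
#'   ("GM" or "WM").
#' @param grid_dims Voxel grid dimensions (three positive integers).
#' @param voxel_size_mm Isotropic voxel edge length in mm (sets the
#'   affine).
#' @param voxel_baseline Mean level of the smooth baseline tissue-density
#'   field (arbitrary map units).
#' @param voxel_noise_sd SD of the per-voxel noise before spatial
#'   smoothing (map units).
#' @param noise_fwhm_vox FWHM, in voxels, of the Gaussian kernel applied
#'   to the noise field (0 disables smoothing).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_subjects = 348L,
                       seed = 20120911L,
                       covariate_margins = list(),
                       icv_mean = 1450, icv_sd = 120,
                       engagement_sd = 0.33,
                       item_loadings = rep(0.7, 8),
                       item_missing_rate = 0,
                       roi_effects = default_roi_effects(),
                       roi_cv = 0.088,
                       roi_covariate_coupling = 1,
                       voxel_covariate_coupling = 1,
                       delta_mean_frac = -0.0125,
                       delta_sd_frac = 0.02,
                       delta_engagement_coupling = 0,
                       blob_spec = list(),
                       grid_dims = c(32L, 32L, 32L),
                       voxel_size_mm = 2,
                       voxel_baseline = 100,
                       voxel_noise_sd = 5,
                       noise_fwhm_vox = 2) {
  margins <- utils::modifyList(default_margins(), covariate_margins)
  if (is.numeric(margins$edu_probs) && sum(margins$edu_probs) > 0)
    margins$edu_probs <- margins$edu_probs / sum(margins$edu_probs)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    covariate_margins = margins,
    icv_mean = icv_mean, icv_sd = icv_sd,
    engagement_sd = engagement_sd,
    item_loadings = item_loadings,
    item_missing_rate = item_missing_rate,
    roi_effects = roi_effects, roi_cv = roi_cv,
    roi_covariate_coupling = roi_covariate_coupling,
    voxel_covariate_coupling = voxel_covariate_coupling,
    delta_mean_frac = delta_mean_frac, delta_sd_frac = delta_sd_frac,
    delta_engagement_coupling = delta_engagement_coupling,
    blob_spec = blob_spec,
    grid_dims = as.integer(grid_dims), voxel_size_mm = voxel_size_mm,
    voxel_baseline = voxel_baseline, voxel_noise_sd = voxel_noise_sd,
    noise_fwhm_vox = noise_fwhm_vox
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default marginal covariate targets
#' @keywords internal
default_margins <- function() {
  list(
    age_mean = 65.2, age_sd = 7.9,
    p_minority = 0.095,
    p_hypertension = 0.517,
    p_diabetes = 0.155,
    p_control = 0.124,
    p_nonright = 0.10,
    # education_levels() order: ref (HS + trade), <HS, HS, college, graduate
    edu_probs = c(0.480, 0.072, 0.259, 0.161, 0.029)
  )
}

#' Default standardized region effects of engagement
#'
#' The default per-region standardized effect sizes used by the synthetic
#' generator: positive associations concentrated in total brain, total and
#' temporal/occipital GM, and corpus callosum, with near-null WM effects.
#'
#' @return Named numeric vector over the 20 canonical regions.
#' @export
default_roi_effects <- function() {
  stats::setNames(
    c(0.037, 0.072, 0.001,
      0.037, 0.083, 0.068, 0.076,
      0.008, 0.021, 0.026, 0.007,
      -0.013, 0.047, 0.045, 0.008,
      0.127, 0.026, -0.004, 0.037, -0.016),
    roi_inventory()$roi
  )
}

config_error <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_sim_config <- function(cfg) {
  m <- cfg$covariate_margins
  chk_prob <- function(name) {
    v <- m[[name]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      config_error(name, "must be a single probability in [0, 1]")
  }
  if (length(cfg$n_subjects) != 1 || is.na(cfg$n_subjects) || cfg$n_subjects < 0)
    config_error("n_subjects", "must be a non-negative integer")
  for (p in c("p_minority", "p_hypertension", "p_diabetes", "p_control",
              "p_nonright")) chk_prob(p)
  if (!is.numeric(m$edu_probs) || length(m$edu_probs) != 5 ||
      any(!is.finite(m$edu_probs)) || any(m$edu_probs < 0) ||
      abs(sum(m$edu_probs) - 1) > 0.02)
    config_error("edu_probs", "must be 5 non-negative probabilities summing to 1")
  for (f in c("age_sd")) if (!is.finite(m[[f]]) || m[[f]] < 0)
    config_error(f, "must be a finite non-negative number")
  if (!is.finite(m$age_mean) || m$age_mean <= 0)
    config_error("age_mean", "must be a finite positive number")
  for (f in c("icv_sd", "engagement_sd", "roi_cv", "delta_sd_frac",
              "voxel_noise_sd", "noise_fwhm_vox", "item_missing_rate",
              "roi_covariate_coupling", "voxel_covariate_coupling"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      config_error(f, "must be a finite non-negative number")
  if (!is.finite(cfg$icv_mean) || cfg$icv_mean <= 0)
    config_error("icv_mean", "must be a finite positive number")
  if (length(cfg$item_loadings) != 8)
    config_error("item_loadings", "must have exactly 8 entries")
  if (any(!is.finite(cfg$item_loadings)) || any(cfg$item_loadings < 0) ||
      any(cfg$item_loadings > 1))
    config_error("item_loadings", "entries must lie in [0, 1]")
  bad <- setdiff(names(cfg$roi_effects), roi_inventory()$roi)
  if (length(bad) > 0)
    config_error("roi_effects",
                 sprintf("has unknown region name(s) %s; valid names are: %s",
                         paste(sQuote(bad), collapse = ", "),
                         paste(roi_inventory()$roi, collapse = "; ")))
  if (length(cfg$grid_dims) != 3 || any(!is.finite(cfg$grid_dims)) ||
      any(cfg$grid_dims < 1))
    config_error("grid_dims", "must be three positive integers")
  if (length(cfg$blob_spec) > 0) {
    for (i in seq_along(cfg$blob_spec)) {
      b <- cfg$blob_spec[[i]]
      if (is.null(b$center) || length(b$center) != 3)
        config_error("blob_spec", sprintf("blob %d needs a voxel center triple", i))
      if (any(b$center < 1) || any(b$center > cfg$grid_dims))
        config_error("blob_spec",
                     sprintf("blob %d center (%s) lies outside the grid", i,
                             paste(b$center, collapse = ", ")))
      if (is.null(b$radius) || b$radius <= 0)
        config_error("blob_spec", sprintf("blob %d needs a positive radius", i))
      if (is.null(b$tissue) || !b$tissue %in% c("GM", "WM"))
        config_error("blob_spec", sprintf("blob %d tissue must be 'GM' or 'WM'", i))
      if (is.null(b$amplitude) || !is.finite(b$amplitude))
        config_error("blob_spec", sprintf("blob %d needs a finite amplitude", i))
    }
  }
  invisible(cfg)
}

# Deterministic RNG substream: each generated object owns an offset from
# the root seed so regenerating one object never shifts the others.
with_substream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  force(expr)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_subjects, "subjects, seed", x$seed, "\n")
  cat("  grid:", paste(x$grid_dims, collapse = "x"),
      " blobs:", length(x$blob_spec),
      " engagement SD:", x$engagement_sd, "\n")
  invisible(x)
}
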