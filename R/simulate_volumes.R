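#' Simulate region-of-interest volumes at two timepoints
#'
#' Generates per-subject volumes for the 20 canonical regions.  The
#' current (timepoint-2) volume of region r is
#' \deqn{V_r = \mu_r + f_r(\mathrm{covariates}) + \beta^*_r \sigma_r z + \epsilon_r,}
#' where `z` is the standardized latent engagement score, \eqn{\beta^*_r}
#' the configured standardized effect, \eqn{\sigma_r =} `roi_cv` \eqn{\times \mu_r}
#' the target marginal SD, and \eqn{f_r} collects covariate
#' contributions (older, hypertensive, diabetic and control subjects have
#' smaller volumes; larger ICV means larger volumes).  The noise SD is set
#' so the marginal SD of \eqn{V_r} equals \eqn{\sigma_r}, which makes the
#' configured \eqn{\beta^*_r} the quantity a covariate-adjusted
#' standardized-coefficient regression recovers.
#'
#' The timepoint-1 volume is `volume_t2 - delta`, where the five-year
#' change `delta` has mean `delta_mean_frac * mu_r` (negative = atrophy),
#' SD `delta_sd_frac * mu_r`, and standardized coupling
#' `delta_engagement_coupling` with engagement (default 0: volume change
#' carries no information about later engagement).
#'
#' @param cohort A cohort data frame from [simulate_cohort()].
#' @param config A [sim_config()] object.
#' @return A `roi_volumes` data frame in long format: `subject_id`,
#'   `roi`, `volume_t1`, `volume_t2`, `delta` (cc).
#' @export
simulate_roi_volumes <- function(cohort, config) {
  validate_sim_config(config)
  inv <- roi_inventory()
  eff <- stats::setNames(rep(0, nrow(inv)), inv$roi)
  eff[names(config$roi_effects)] <- config$roi_effects
  n <- nrow(cohort)
  m <- config$covariate_margins
  z <- if (n > 0) cohort$engagement / config$engagement_sd else numeric(0)

  with_substream(config, 2L, {
    res <- vector("list", nrow(inv))
    for (r in seq_len(nrow(inv))) {
      mu <- inv$mean_cc[r]
      sd_r <- config$roi_cv * mu
      # covariate couplings, proportional to the region mean
      cc <- config$roi_covariate_coupling
      c_age <- -0.004 * mu * cc     # cc per year above the mean age
      c_htn <- -0.02 * mu * cc
      c_dm  <- -0.02 * mu * cc
      c_ctl <- -0.034 * mu * cc
      c_icv <- 0.05 * mu * cc       # cc per SD of ICV
      f <- c_age * (cohort$age - m$age_mean) +
        c_htn * (cohort$hypertension - m$p_hypertension) +
        c_dm * (cohort$diabetes - m$p_diabetes) +
        c_ctl * (cohort$is_control - m$p_control) +
        c_icv * (cohort$icv - config$icv_mean) / config$icv_sd
      var_cov <- (c_age * m$age_sd)^2 +
        c_htn^2 * m$p_hypertension * (1 - m$p_hypertension) +
        c_dm^2 * m$p_diabetes * (1 - m$p_diabetes) +
        c_ctl^2 * m$p_control * (1 - m$p_control) + c_icv^2
      noise_var <- max(sd_r^2 * (1 - eff[r]^2) - var_cov, 0)
      v2 <- mu + f + eff[r] * sd_r * z +
        stats::rnorm(n, 0, sqrt(noise_var))

      d_mu <- config$delta_mean_frac * mu
      d_sd <- config$delta_sd_frac * mu
      rho <- config$delta_engagement_coupling
      delta <- d_mu + rho * d_sd * z +
        stats::rnorm(n, 0, d_sd * sqrt(max(0, 1 - rho^2)))
      res[[r]] <- data.frame(
        subject_id = cohort$subject_id, roi = inv$roi[r],
        volume_t1 = v2 - delta, volume_t2 = v2, delta = delta,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    structure(out, class = c("roi_volumes", "data.frame"))
  })
}

gaussian_kernel_1d <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix with edge renormalization, for separable
# smoothing along one array dimension.
conv_matrix <- function(d, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, d, d)
  for (off in -r:r) {
    i <- seq_len(d)
    j <- i + off
    ok <- j >= 1 & j <= d
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + kernel[off + r + 1L]
  }
  sweep(K, 1, rowSums(K), "/")
}

#' Smooth a 3-D array with a separable Gaussian kernel
#'
#' @param arr 3-D numeric array.
#' @param fwhm Kernel full width at half maximum, in voxels.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_gaussian_3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  d <- dim(arr)
  k <- gaussian_kernel_1d(fwhm)
  # dim 1
  x <- conv_matrix(d[1], k) %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(x, d)
  # dim 2
  a <- aperm(arr, c(2, 1, 3))
  x <- conv_matrix(d[2], k) %*% matrix(a, d[2], d[1] * d[3])
  arr <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
  # dim 3
  a <- aperm(arr, c(3, 1, 2))
  x <- conv_matrix(d[3], k) %*% matrix(a, d[3], d[1] * d[2])
  aperm(array(x, d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Simulate a stack of tissue-density maps
#'
#' Generates one non-negative 3-D tissue-density grid per subject on a
#' shared voxel grid and affine:
#' a smooth baseline field (identical across subjects), a per-subject
#' global scaling driven by ICV and age, configured spherical effect
#' blobs whose intensity is `amplitude *` standardized engagement inside
#' the support, and spatially smoothed Gaussian noise.  The smoothed
#' noise field is rescaled so its marginal per-voxel SD equals
#' `voxel_noise_sd`, which makes blob amplitudes interpretable as
#' per-voxel effects in noise-SD units.
#'
#' @param cohort A cohort data frame.
#' @param config A [sim_config()] object; only blobs whose `tissue`
#'   matches `tissue` are embedded.
#' @param tissue `"GM"` or `"WM"`; tags the stack and selects blobs (the
#'   two tissue classes are generated from distinct RNG substreams).
#' @return A [voxel_stack] object.
#' @export
simulate_voxel_maps <- function(cohort, config, tissue = c("GM", "WM")) {
  validate_sim_config(config)
  tissue <- match.arg(tissue)
  d <- config$grid_dims
  nv <- prod(d)
  n <- nrow(cohort)
  m <- config$covariate_margins
  z <- if (n > 0) cohort$engagement / config$engagement_sd else numeric(0)

  with_substream(config, if (tissue == "GM") 3L else 5L, {
    # smooth baseline shared by all subjects
    base <- array(stats::rnorm(nv, 0, 1), d)
    base <- smooth_gaussian_3d(base, max(config$noise_fwhm_vox, 2))
    base <- config$voxel_baseline * (1 + 0.1 * base / max(stats::sd(base), 1e-12))

    blob_field <- array(0, d)
    for (b in config$blob_spec) {
      if (b$tissue != tissue) next
      idx <- blob_support(d, b$center, b$radius)
      blob_field[idx] <- blob_field[idx] + b$amplitude
    }

    vc <- config$voxel_covariate_coupling
    scale <- 1 + vc * (0.02 * (cohort$icv - config$icv_mean) / config$icv_sd -
                         0.002 * (cohort$age - m$age_mean))

    maps <- matrix(0, n, nv)
    bvec <- as.numeric(base)
    fvec <- as.numeric(blob_field)
    for (i in seq_len(n)) {
      noise <- array(stats::rnorm(nv, 0, 1), d)
      if (config$noise_fwhm_vox > 0) {
        sm <- smooth_gaussian_3d(noise, config$noise_fwhm_vox)
        # restore unit marginal SD lost to smoothing, then scale
        k <- gaussian_kernel_1d(config$noise_fwhm_vox)
        sm <- sm / sqrt(sum(k^2))^3
        noise <- sm
      }
      maps[i, ] <- pmax(scale[i] * bvec + fvec * z[i] +
                          config$voxel_noise_sd * as.numeric(noise), 0)
    }
    voxel_stack(maps, dims = d, subject_id = cohort$subject_id,
                tissue = tissue,
                affine = diag(c(rep(config$voxel_size_mm, 3), 1)))
  })
}

#' Linear indices of a spherical blob support
#' @param dims grid dimensions
#' @param center voxel triple (1-based)
#' @param radius radius in voxels
#' @return Integer vector of linear voxel indices.
#' @export
blob_support <- function(dims, center, radius) {
  i <- seq_len(dims[1]); j <- seq_len(dims[2]); k <- seq_len(dims[3])
  di2 <- (i - center[1])^2
  dj2 <- (j - center[2])^2
  dk2 <- (k - center[3])^2
  dist2 <- outer(outer(di2, dj2, "+"), dk2, "+")
  which(dist2 <= radius^2)
}
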