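#' Simulate a study cohort
#'
#' Draws per-subject covariates and a latent engagement score with the
#' marginal structure of the study population: age from a normal
#' distribution, binary race/hypertension/diabetes/control/handedness
#' indicators from the configured proportions, education from a five-level
#' multinomial, and intracranial volume (ICV) from a normal distribution.
#' The latent engagement score is mildly coupled to age, education and
#' control status (older, more educated, and control subjects are more
#' engaged), then rescaled so its marginal SD matches
#' `config$engagement_sd` and its mean is 0.
#'
#' Two bookkeeping flags are drawn for the exclusion cascade:
#' `quality_flag_mri` (poor-quality scan) and `missing_engagement`; both
#' default to all-`FALSE` and are set by [simulate_exclusion_flags()] or
#' by the caller when a cascade is to be exercised.
#'
#' @param config A [sim_config()] object.
#' @return A `cohort` data frame (one row per subject) with columns
#'   `subject_id`, `age`, `education` (factor, reference level first),
#'   `race_minority`, `hypertension`, `diabetes`, `handedness`
#'   (`"right"`/`"nonright"`), `is_control`, `icv`, `engagement` (latent
#'   score), `quality_flag_mri`, `missing_engagement`.
#' @seealso [simulate_items()], [simulate_roi_volumes()],
#'   [simulate_voxel_maps()]
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_subjects
  m <- config$covariate_margins
  empty_factor <- factor(character(0), levels = education_levels())
  if (n == 0) {
    out <- data.frame(
      subject_id = character(0), age = numeric(0),
      education = empty_factor,
      race_minority = integer(0), hypertension = integer(0),
      diabetes = integer(0), handedness = character(0),
      is_control = integer(0), icv = numeric(0), engagement = numeric(0),
      quality_flag_mri = logical(0), missing_engagement = logical(0),
      stringsAsFactors = FALSE
    )
    return(structure(out, class = c("cohort", "data.frame")))
  }
  with_substream(config, 0L, {
    age <- stats::rnorm(n, m$age_mean, m$age_sd)
    education <- factor(
      sample(education_levels(), n, replace = TRUE, prob = m$edu_probs),
      levels = education_levels()
    )
    race_minority <- stats::rbinom(n, 1L, m$p_minority)
    hypertension <- stats::rbinom(n, 1L, m$p_hypertension)
    diabetes <- stats::rbinom(n, 1L, m$p_diabetes)
    handedness <- ifelse(stats::rbinom(n, 1L, m$p_nonright) == 1L,
                         "nonright", "right")
    is_control <- stats::rbinom(n, 1L, m$p_control)
    icv <- stats::rnorm(n, config$icv_mean, config$icv_sd)

    # Engagement: latent normal plus weak covariate coupling (older, more
    # educated and control subjects slightly more engaged), rescaled to the
    # configured SD and centered at 0.
    edu_rank <- match(as.character(education),
                      c("<High school", "High school",
                        "High school + trade school", "College degree",
                        "Graduate degree")) - 3
    lin <- 0.10 * (age - m$age_mean) / max(m$age_sd, 1e-8) +
      0.10 * edu_rank + 0.30 * is_control
    lin <- lin - mean(lin)
    z <- stats::rnorm(n)
    raw <- lin + sqrt(max(0, 1 - stats::var(lin))) * z
    engagement <- config$engagement_sd * (raw - mean(raw)) /
      max(stats::sd(raw), 1e-12)

    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, education = education, race_minority = race_minority,
      hypertension = hypertension, diabetes = diabetes,
      handedness = handedness, is_control = is_control, icv = icv,
      engagement = engagement,
      quality_flag_mri = rep(FALSE, n),
      missing_engagement = rep(FALSE, n),
      stringsAsFactors = FALSE
    )
    structure(out, class = c("cohort", "data.frame"))
  })
}

#' Flag subjects for the exclusion cascade
#'
#' Marks `n_quality` subjects with a poor-quality-scan flag and
#' `n_missing` *other* subjects as missing the engagement measure, so the
#' two exclusion reasons are disjoint unless the cohort is too small to
#' keep them apart.
#'
#' @param cohort A cohort data frame.
#' @param config A [sim_config()] object (supplies the RNG substream).
#' @param n_quality,n_missing Counts of subjects to flag.
#' @return The cohort with updated `quality_flag_mri` /
#'   `missing_engagement` columns.
#' @export
simulate_exclusion_flags <- function(cohort, config, n_quality = 9L,
                                     n_missing = 5L) {
  n <- nrow(cohort)
  if (n_quality + n_missing > n)
    stop("cannot flag more subjects than the cohort contains", call. = FALSE)
  with_substream(config, 4L, {
    idx <- sample.int(n, n_quality + n_missing)
    cohort$quality_flag_mri <- seq_len(n) %in% idx[seq_len(n_quality)]
    cohort$missing_engagement <- seq_len(n) %in%
      idx[n_quality + seq_len(n_missing)]
    cohort
  })
}

#' Simulate ordinal engagement item responses
#'
#' Generates the eight ordinal items from a one-factor graded-response
#' scheme: each item's latent propensity is
#' `loading * z + sqrt(1 - loading^2) * unique noise`, where `z` is the
#' subject's standardized latent engagement score, and the propensity is
#' discretized through equally spaced thresholds into the item's ordinal
#' range (0..`n_levels - 1`, see [engagement_items()]).  Missing responses
#' are injected completely at random at `config$item_missing_rate`.
#'
#' @param cohort A cohort data frame with an `engagement` column.
#' @param config A [sim_config()] object.
#' @return Data frame with `subject_id` and one integer column per item.
#' @export
simulate_items <- function(cohort, config) {
  validate_sim_config(config)
  items <- engagement_items()
  lam <- config$item_loadings
  n <- nrow(cohort)
  z <- if (n > 0 && stats::sd(cohort$engagement) > 0) {
    (cohort$engagement - mean(cohort$engagement)) / stats::sd(cohort$engagement)
  } else rep(0, n)
  with_substream(config, 1L, {
    out <- data.frame(subject_id = cohort$subject_id,
                      stringsAsFactors = FALSE)
    for (j in seq_len(8)) {
      prop <- lam[j] * z + sqrt(1 - lam[j]^2) * stats::rnorm(n)
      k <- items$n_levels[j]
      # equally spaced interior thresholds spanning the bulk of the
      # propensity distribution
      br <- c(-Inf, seq(-2, 2, length.out = k - 1), Inf)
      resp <- as.integer(cut(prop, breaks = br)) - 1L
      if (config$item_missing_rate > 0) {
        miss <- stats::runif(n) < config$item_missing_rate
        resp[miss] <- NA_integer_
      }
      out[[items$item[j]]] <- resp
    }
    out
  })
}
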