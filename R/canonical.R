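#' Canonical region-of-interest inventory
#'
#' The 20 non-mutually-exclusive anatomical regions analysed by the
#' pipeline: total brain, total gray matter (GM), total white matter (WM),
#' the four lobar subdivisions of each tissue class, and nine smaller
#' structures.  `mean_cc` gives the default population mean volume in cc
#' used by the synthetic generator; `group` records the block each region
#' belongs to (global, GM lobe, WM lobe, structure).
#'
#' @return A data frame with columns `roi`, `mean_cc`, `group`, in
#'   canonical reporting order.
#' @export
#' @examples
#' roi_inventory()
roi_inventory <- function() {
  data.frame(
    roi = c(
      "Total brain volume", "Total gray matter (GM)", "Total white matter (WM)",
      "Frontal GM", "Temporal GM", "Parietal GM", "Occipital GM",
      "Frontal WM", "Temporal WM", "Parietal WM", "Occipital WM",
      "Cerebellum", "Medial structures", "Cingulate gyrus", "Insula",
      "Corpus callosum", "Internal capsule", "Hippocampus", "Amygdala",
      "Entorhinal cortex"
    ),
    mean_cc = c(
      1137.96, 534.14, 603.82,
      134.85, 96.58, 65.40, 45.56,
      201.47, 119.03, 106.08, 58.22,
      119.63, 80.63, 21.02, 13.94,
      11.89, 9.85, 7.42, 2.43, 2.37
    ),
    group = c(
      rep("global", 3), rep("gm_lobe", 4), rep("wm_lobe", 4),
      rep("structure", 9)
    ),
    stringsAsFactors = FALSE
  )
}

#' Social-engagement item definitions
#'
#' The eight ordinal items of the social-engagement subscale: frequency of
#' contact with friends/relatives, grooming to go out, volunteer work,
#' meals out, club/organization meetings, social outings, shopping, and
#' recreational activity.  `n_levels` is the number of ordinal response
#' categories (the contact item is asked per week, the rest per month).
#'
#' @return A data frame with columns `item`, `recall` ("week"/"month") and
#'   `n_levels`.
#' @export
engagement_items <- function() {
  data.frame(
    item = c("contact_friends", "groomed_to_go_out", "volunteer_work",
             "meals_out", "club_meetings", "social_outings",
             "shopping", "recreation"),
    recall = c("week", rep("month", 7)),
    n_levels = c(8L, rep(5L, 7)),
    stringsAsFactors = FALSE
  )
}

#' Education categories
#'
#' Five-level educational attainment coding; "High school + trade school"
#' is the reference level in all design matrices.
#'
#' @return Character vector of the five levels, reference first.
#' @export
education_levels <- function() {
  c("High school + trade school", "<High school", "High school",
    "College degree", "Graduate degree")
}
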