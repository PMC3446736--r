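# Per-region OLS models: cross-sectional (engagement -> volume),
# effect-modification cross-product tests, and temporal-reversal models
# (engagement regressed on five-year volume change).

# Shared OLS core via stats::lm on an explicit numeric matrix; returns the
# row for the focal (last) column.
ols_focal <- function(X, y, focal) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(y ~ 0 + X)
  sm <- summary(fit)$coefficients
  rownames(sm) <- colnames(X)
  list(fit = fit,
       b = sm[focal, 1], se = sm[focal, 2],
       t = sm[focal, 3], p = sm[focal, 4],
       df = fit$df.residual)
}

# Pivot the long volume table to a subjects x regions matrix aligned to
# the subject order of the design matrix; only regions present in the
# table are returned, in canonical order.
align_volumes <- function(volumes, subject_ids, column) {
  rois <- intersect(roi_inventory()$roi, unique(volumes$roi))
  if (length(rois) == 0)
    stop("no canonical region names found in the volume table", call. = FALSE)
  out <- matrix(NA_real_, length(subject_ids), length(rois),
                dimnames = list(subject_ids, rois))
  idx <- cbind(match(volumes$subject_id, subject_ids),
               match(volumes$roi, rois))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  out[idx[keep, , drop = FALSE]] <- volumes[[column]][keep]
  out
}

align_engagement <- function(engagement, subject_ids) {
  if (!is.null(names(engagement))) {
    e <- unname(engagement[subject_ids])
    if (anyNA(e))
      stop("engagement scores missing for subject(s): ",
           paste(subject_ids[is.na(e)], collapse = ", "), call. = FALSE)
    e
  } else {
    if (length(engagement) != length(subject_ids))
      stop("unnamed engagement vector must match the design row count",
           call. = FALSE)
    as.numeric(engagement)
  }
}

#' Fit per-region cross-sectional volume models
#'
#' For each region, fits OLS of the current (timepoint-2) volume on the
#' covariate design plus the engagement score, and reports the raw
#' engagement coefficient (cc per score unit), its standardized version
#' `beta_std = b * SD(engagement) / SD(volume)` (dimensionless), the
#' classical SE, t and two-sided p at the residual df.  No
#' multiple-comparison adjustment is applied across the 20 regions; raw
#' SEs and p-values are reported.
#'
#' @param volumes A `roi_volumes` long data frame (needs `volume_t2`).
#' @param design Design matrix from [build_design_matrix()] (row names =
#'   subject ids).
#' @param engagement Engagement scores: named vector (names = subject
#'   ids) or vector aligned with the design rows.
#' @return Data frame of class `roi_results`, one row per region in
#'   canonical order: `roi`, `mean_volume`, `b`, `beta_std`, `se`, `t`,
#'   `p`, `n`, `direction = "forward"`.
#' @export
fit_roi_models <- function(volumes, design, engagement) {
  ids <- rownames(design)
  eng <- align_engagement(engagement, ids)
  V <- align_volumes(volumes, ids, "volume_t2")
  res <- lapply(colnames(V), function(roi) {
    y <- V[, roi]
    ok <- !is.na(y)
    X <- cbind(design[ok, , drop = FALSE], engagement = eng[ok])
    if (nrow(X) <= ncol(X) + 1)
      stop("too few subjects (", nrow(X), ") for ", ncol(X),
           " design columns in region ", roi, call. = FALSE)
    f <- ols_focal(X, y[ok], "engagement")
    data.frame(roi = roi, mean_volume = mean(y[ok]),
               b = f$b,
               beta_std = f$b * stats::sd(eng[ok]) / stats::sd(y[ok]),
               se = f$se, t = f$t, p = f$p, n = sum(ok),
               direction = "forward", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("roi_results", "data.frame"))
}

#' Fit temporal-reversal models
#'
#' Reverses the cross-sectional direction to probe temporality: for each
#' region, fits OLS of the engagement score (measured at the second
#' timepoint) on the covariate design plus the five-year volume change
#' `delta = volume_t2 - volume_t1`.  `beta_std` standardizes the change
#' coefficient against the engagement SD.  A null result here is
#' evidence against reverse causation (shrinking volumes driving
#' disengagement).
#'
#' @inheritParams fit_roi_models
#' @return `roi_results` data frame with `direction = "reversed"`;
#'   `mean_volume` reports the mean change.
#' @export
fit_reversed_models <- function(volumes, design, engagement) {
  ids <- rownames(design)
  eng <- align_engagement(engagement, ids)
  if (anyNA(volumes$volume_t1)) {
    bad <- unique(volumes$subject_id[is.na(volumes$volume_t1)])
    stop("missing timepoint-1 volumes for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  D <- align_volumes(volumes, ids, "volume_t2") -
    align_volumes(volumes, ids, "volume_t1")
  res <- lapply(colnames(D), function(roi) {
    d <- D[, roi]
    ok <- !is.na(d)
    X <- cbind(design[ok, , drop = FALSE], delta_roi = d[ok])
    f <- ols_focal(X, eng[ok], "delta_roi")
    data.frame(roi = roi, mean_volume = mean(d[ok]),
               b = f$b,
               beta_std = f$b * stats::sd(d[ok]) / stats::sd(eng[ok]),
               se = f$se, t = f$t, p = f$p, n = sum(ok),
               direction = "reversed", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("roi_results", "data.frame"))
}

# Design columns forming each nameable modifier block.
modifier_columns <- function(design, modifier) {
  cn <- colnames(design)
  block <- switch(modifier,
    age = "age_c",
    education = grep("^edu_", cn, value = TRUE),
    race = "race_minority",
    cvd_risk = c("hypertension", "diabetes"),
    control = "is_control",
    modifier  # literal column name fallback
  )
  missing <- setdiff(block, cn)
  if (length(missing) > 0 || length(block) == 0)
    stop("modifier not present in design: ", modifier, call. = FALSE)
  block
}

#' Test effect modification by a covariate
#'
#' For each region, compares the cross-sectional model with and without
#' engagement-by-modifier cross-product terms and reports the joint
#' F-test p-value (a single-df Wald test when the modifier is one
#' column).  Recognized modifier names: `"age"`, `"education"`,
#' `"race"`, `"cvd_risk"` (hypertension + diabetes jointly), `"control"`,
#' or any literal design column name.
#'
#' @inheritParams fit_roi_models
#' @param modifier Modifier name (see Details).
#' @return Data frame: `roi`, `modifier`, `F`, `df1`, `df2`, `p`.
#' @export
test_effect_modification <- function(volumes, design, engagement, modifier) {
  ids <- rownames(design)
  eng <- align_engagement(engagement, ids)
  block <- modifier_columns(design, modifier)
  for (bcol in block) {
    if (stats::sd(design[, bcol]) == 0)
      stop("modifier column has zero variance: ", bcol, call. = FALSE)
  }
  V <- align_volumes(volumes, ids, "volume_t2")
  res <- lapply(colnames(V), function(roi) {
    y <- V[, roi]
    ok <- !is.na(y)
    X0 <- cbind(design[ok, , drop = FALSE], engagement = eng[ok])
    inter <- design[ok, block, drop = FALSE] * eng[ok]
    colnames(inter) <- paste0("engagement_x_", block)
    X1 <- cbind(X0, inter)
    f0 <- stats::lm(y[ok] ~ 0 + X0)
    f1 <- stats::lm(y[ok] ~ 0 + X1)
    a <- stats::anova(f0, f1)
    data.frame(roi = roi, modifier = modifier,
               F = a$F[2], df1 = a$Df[2], df2 = f1$df.residual,
               p = a$`Pr(>F)`[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.roi_results <- function(x, digits = 3, ...) {
  cat(sprintf("Per-region %s models (n = %d)\n",
              x$direction[1], x$n[1]))
  df <- data.frame(roi = x$roi,
                   mean = round(x$mean_volume, 2),
                   beta_std = round(x$beta_std, 3),
                   p = signif(x$p, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
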