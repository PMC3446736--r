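#' Apply the study exclusion cascade
#'
#' Removes subjects in two ordered stages: first those whose MRI failed
#' quality review (`quality_flag_mri`), then those missing the engagement
#' measure (`missing_engagement`).  A subject flagged for both reasons is
#' removed at the quality stage only, so stage counts partition the
#' removals.  The operation is idempotent.
#'
#' @param raw A cohort data frame with `quality_flag_mri` and
#'   `missing_engagement` logical columns and unique `subject_id`.
#' @return A list with `cohort` (retained subjects) and `log`, a data
#'   frame with one row per stage (`stage`, `n_before`, `n_after`,
#'   `n_removed`) carrying the removed ids in attribute `removed_ids`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 30, seed = 7)
#' coh <- simulate_exclusion_flags(simulate_cohort(cfg), cfg,
#'                                 n_quality = 2, n_missing = 1)
#' apply_exclusions(coh)$log
apply_exclusions <- function(raw) {
  if (anyDuplicated(raw$subject_id))
    stop("duplicated subject_id in cohort: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]),
               collapse = ", "), call. = FALSE)
  stages <- list(
    c(name = "mri_quality", flag = "quality_flag_mri"),
    c(name = "missing_engagement", flag = "missing_engagement")
  )
  cur <- raw
  log <- data.frame(stage = character(0), n_before = integer(0),
                    n_after = integer(0), n_removed = integer(0),
                    stringsAsFactors = FALSE)
  removed_ids <- list()
  for (s in stages) {
    drop <- as.logical(cur[[s[["flag"]]]])
    drop[is.na(drop)] <- FALSE
    nxt <- cur[!drop, , drop = FALSE]
    log <- rbind(log, data.frame(
      stage = s[["name"]], n_before = nrow(cur), n_after = nrow(nxt),
      n_removed = sum(drop), stringsAsFactors = FALSE
    ))
    removed_ids[[s[["name"]]]] <- cur$subject_id[drop]
    cur <- nxt
  }
  rownames(cur) <- NULL
  attr(log, "removed_ids") <- removed_ids
  list(cohort = cur, log = log)
}

#' Compute a factor-based score from ordinal items
#'
#' One-factor scoring of a set of ordinal items: items are standardized,
#' loadings are estimated by iterated principal-axis factoring of the
#' Pearson correlation matrix (communalities on the diagonal, leading
#' eigenvector updates), and each subject's score is the loading-weighted
#' sum of their standardized item responses, centered to mean 0.  The
#' loading sign is fixed so the loading sum is positive, so a higher
#' score always means more of the construct.  The computation is fully
#' deterministic for fixed input.
#'
#' Subjects missing any item receive an `NA` score (to be removed by the
#' exclusion cascade).  Items with zero variance are dropped with a
#' warning; if more than four of the eight items are degenerate the
#' scoring aborts.
#'
#' @param items Data frame with a `subject_id` column and one ordinal
#'   column per item.
#' @param min_complete Minimum number of complete records required to
#'   estimate the correlation matrix.
#' @return Named numeric vector of scores (names = subject ids), with the
#'   estimated loadings in attribute `"loadings"`.
#' @export
factor_based_score <- function(items, min_complete = 25L) {
  item_cols <- setdiff(names(items), "subject_id")
  X <- as.matrix(items[, item_cols, drop = FALSE])
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X)
  if (sum(complete) < min_complete)
    stop(sprintf("need at least %d complete records to score (have %d)",
                 min_complete, sum(complete)), call. = FALSE)
  sds <- apply(X[complete, , drop = FALSE], 2, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  if (sum(degenerate) > 4)
    stop("more than 4 items have zero variance; cannot score", call. = FALSE)
  if (any(degenerate)) {
    warning("dropping zero-variance item(s): ",
            paste(item_cols[degenerate], collapse = ", "), call. = FALSE)
    X <- X[, !degenerate, drop = FALSE]
    item_cols <- item_cols[!degenerate]
  }
  mu <- colMeans(X[complete, , drop = FALSE])
  sds <- apply(X[complete, , drop = FALSE], 2, stats::sd)
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
  R <- stats::cor(Z[complete, , drop = FALSE])
  loadings <- principal_axis_loadings(R)
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- item_cols
  score <- as.numeric(Z %*% loadings)
  score <- score - mean(score, na.rm = TRUE)
  names(score) <- items$subject_id
  attr(score, "loadings") <- loadings
  score
}

# Iterated principal-axis factoring, one factor.  Communalities start at
# the squared multiple correlations and are updated from the leading
# eigenpair of the reduced correlation matrix until convergence.
principal_axis_loadings <- function(R, tol = 1e-9, max_iter = 500L) {
  p <- ncol(R)
  h2 <- tryCatch({
    Rinv <- solve(R)
    pmin(pmax(1 - 1 / diag(Rinv), 0.05), 0.99)
  }, error = function(e) {
    apply(abs(R - diag(p)), 2, max)
  })
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    l <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    h2_new <- pmin(l^2, 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  Rh <- R
  diag(Rh) <- h2
  e <- eigen(Rh, symmetric = TRUE)
  e$vectors[, 1] * sqrt(max(e$values[1], 0))
}

#' Build the covariate design matrix
#'
#' Constructs the right-hand side shared by every model in the pipeline:
#' intercept, age centered at the sample mean, four education indicators
#' (reference = "High school + trade school"), minority-race indicator,
#' ICV, hypertension, diabetes, non-right-handedness indicator, and
#' control-status indicator — 12 columns with binary handedness.  The
#' focal exposure (engagement) is *not* included; each model appends it
#' (or a volume-change column) itself.  Indicators for category levels
#' absent from the cohort are dropped with a warning to preserve full
#' column rank.
#'
#' @param cohort A post-exclusion cohort data frame.
#' @return Numeric matrix with subject ids as row names and attributes
#'   `rank` (QR rank) and `age_center` (centering constant, years).
#' @export
build_design_matrix <- function(cohort) {
  n <- nrow(cohort)
  age_center <- mean(cohort$age)
  cols <- list(`(Intercept)` = rep(1, n),
               age_c = cohort$age - age_center)
  edu <- factor(as.character(cohort$education), levels = education_levels())
  for (lev in education_levels()[-1]) {
    ind <- as.numeric(edu == lev)
    nm <- paste0("edu_", gsub("[^A-Za-z]+", "_", tolower(lev)))
    if (sum(ind) == 0) {
      warning("education level absent from cohort, dropping indicator: ",
              lev, call. = FALSE)
      next
    }
    cols[[nm]] <- ind
  }
  binary_cols <- list(
    race_minority = as.numeric(cohort$race_minority),
    icv = cohort$icv,
    hypertension = as.numeric(cohort$hypertension),
    diabetes = as.numeric(cohort$diabetes),
    handedness_nonright = as.numeric(cohort$handedness == "nonright"),
    is_control = as.numeric(cohort$is_control)
  )
  for (nm in names(binary_cols)) {
    v <- binary_cols[[nm]]
    if (nm != "icv" && length(unique(v)) < 2) {
      warning("covariate constant in cohort, dropping column: ", nm,
              call. = FALSE)
      next
    }
    cols[[nm]] <- v
  }
  X <- do.call(cbind, cols)
  rownames(X) <- cohort$subject_id
  attr(X, "rank") <- qr(X)$rank
  attr(X, "age_center") <- age_center
  X
}
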