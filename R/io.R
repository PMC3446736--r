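# File interfaces: CSV tables, NIfTI-1 map stacks with a manifest,
# JSON exclusion logs, and report rendering.

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `read_cohort` returns the cohort with the education factor and
#'   flag columns restored.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("education" %in% names(df))
    df$education <- factor(df$education, levels = education_levels())
  for (fl in c("quality_flag_mri", "missing_engagement"))
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  structure(df, class = c("cohort", "data.frame"))
}

#' Write / read a long ROI volume table as CSV
#' @param volumes `roi_volumes` data frame.
#' @param path CSV path.
#' @export
write_roi_volumes <- function(volumes, path) {
  utils::write.csv(volumes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_volumes
#' @export
read_roi_volumes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("roi_volumes", "data.frame"))
}

#' Write a voxel stack as per-subject NIfTI-1 files plus a manifest
#'
#' One float NIfTI-1 file per subject, named `<subject_id>.nii.gz`, and a
#' tab-separated manifest (`subject_id`, `path`, `tissue`) the reader
#' consumes.  The stack's (diagonal) affine is carried through the NIfTI
#' pixdim fields.
#'
#' @param stack A [voxel_stack].
#' @param dir Output directory (created if absent).
#' @param manifest Manifest filename within `dir`.
#' @return Path to the manifest file.
#' @export
write_voxel_stack <- function(stack, dir, manifest = "manifest.tsv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- diag(stack$affine)[1:3]
  if (max(abs(stack$affine - diag(c(vox, 1)))) > 1e-8)
    stop("only diagonal affines are supported by the NIfTI writer",
         call. = FALSE)
  paths <- character(nrow(stack$data))
  for (i in seq_len(nrow(stack$data))) {
    img <- RNifti::asNifti(array(stack$data[i, ], stack$dims))
    RNifti::pixdim(img) <- vox
    paths[i] <- file.path(dir, paste0(stack$subject_id[i], ".nii.gz"))
    RNifti::writeNifti(img, paths[i])
  }
  mf <- data.frame(subject_id = stack$subject_id, path = paths,
                   tissue = stack$tissue, stringsAsFactors = FALSE)
  mpath <- file.path(dir, manifest)
  utils::write.table(mf, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}

#' Read a voxel stack from a manifest
#'
#' Loads every NIfTI file listed in a tab-separated manifest
#' (`subject_id`, `path`, optional `tissue`), verifies that all images
#' share dimensions and affine, and assembles a [voxel_stack] in
#' manifest order.  Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest TSV path.
#' @return A [voxel_stack].
#' @export
read_voxel_manifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(mf)))
    stop("manifest needs 'subject_id' and 'path' columns", call. = FALSE)
  base <- dirname(path)
  dims <- NULL; affine <- NULL
  data <- NULL
  for (i in seq_len(nrow(mf))) {
    f <- mf$path[i]
    if (!file.exists(f)) f <- file.path(base, mf$path[i])
    if (!file.exists(f))
      stop("missing image file for subject ", mf$subject_id[i], ": ",
           mf$path[i], call. = FALSE)
    img <- RNifti::readNifti(f)
    a <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
    d <- dim(img)
    if (is.null(dims)) {
      dims <- d; affine <- a
      data <- matrix(0, nrow(mf), prod(d))
    } else {
      if (!identical(as.integer(d), as.integer(dims)))
        stop("image dimensions of subject ", mf$subject_id[i],
             " differ from the rest of the stack", call. = FALSE)
      if (max(abs(a - affine)) > 1e-6)
        stop("affine of subject ", mf$subject_id[i],
             " differs from the rest of the stack", call. = FALSE)
    }
    data[i, ] <- as.numeric(img)
  }
  tissue <- if ("tissue" %in% names(mf)) mf$tissue[1] else "GM"
  voxel_stack(data, dims = dims, subject_id = mf$subject_id,
              tissue = tissue, affine = affine)
}

#' Write a t-map as NIfTI-1
#' @param map A `stat_map`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$t)
  RNifti::pixdim(img) <- diag(map$affine)[1:3]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read the exclusion log as JSON
#' @param log Exclusion log from [apply_exclusions()].
#' @param path JSON path.
#' @export
write_exclusion_log <- function(log, path) {
  payload <- lapply(seq_len(nrow(log)), function(i) list(
    stage = log$stage[i], n_before = log$n_before[i],
    n_after = log$n_after[i], n_removed = log$n_removed[i],
    removed_ids = attr(log, "removed_ids")[[log$stage[i]]]
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Persist a permutation null distribution as TSV (for audit)
#' @param null A `null_distribution`.
#' @param path TSV path.
#' @export
write_null_distribution <- function(null, path) {
  utils::write.table(
    data.frame(repetition = seq_along(null$max_sizes),
               max_cluster_size = null$max_sizes),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render report tables
#'
#' Shapes model outputs into the pipeline's reporting layout: per-region
#' tables carry the region, mean volume, standardized coefficient and
#' p-value with a `significant` flag (p <= 0.05) in canonical region
#' order; cluster tables carry centroid mm coordinates, peak t,
#' uncorrected peak p, size, and the permutation-adjusted cluster p with
#' the same flag.  Optionally writes each table as TSV.
#'
#' @param roi_results A `roi_results` data frame (or `NULL`).
#' @param cluster_sets A `cluster_set`, or a named list of them (e.g.,
#'   one per tissue), or `NULL`.
#' @param dir Optional output directory for TSV files.
#' @return Named list of report data frames.
#' @export
render_report <- function(roi_results = NULL, cluster_sets = NULL,
                          dir = NULL) {
  out <- list()
  if (!is.null(roi_results)) {
    out$roi <- data.frame(
      roi = roi_results$roi,
      mean_volume_cc = round(roi_results$mean_volume, 2),
      standardized_coefficient = round(roi_results$beta_std, 3),
      p_value = round(roi_results$p, 3),
      significant = roi_results$p <= 0.05,
      direction = roi_results$direction,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(cluster_sets)) {
    if (inherits(cluster_sets, "cluster_set"))
      cluster_sets <- stats::setNames(list(cluster_sets),
                                      attr(cluster_sets, "tissue") %||% "GM")
    for (nm in names(cluster_sets)) {
      cs <- cluster_sets[[nm]]
      out[[paste0("clusters_", nm)]] <- data.frame(
        x = round(cs$x_mm, 1), y = round(cs$y_mm, 1), z = round(cs$z_mm, 1),
        max_t = round(cs$peak_t, 2),
        unadjusted_p = signif(cs$peak_p, 2),
        cluster_size = cs$size,
        cluster_p = round(cs$cluster_p, 2),
        significant = !is.na(cs$cluster_p) & cs$cluster_p <= 0.05,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out))
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
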