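#' Voxel map stack
#'
#' Container for a set of subject-level 3-D tissue-density maps sharing
#' one grid and affine.  Maps are stored as an `n_subjects x n_voxels`
#' matrix (column-major voxel order, as in the underlying arrays), which
#' is the layout the voxel-wise GLM consumes directly.
#'
#' @param data Numeric matrix, one row per subject, `prod(dims)` columns.
#' @param dims Integer triple of grid dimensions.
#' @param subject_id Character vector of subject identifiers (row order).
#' @param tissue `"GM"` or `"WM"`.
#' @param affine 4x4 voxel-to-mm affine (RAS+, 0-based voxel indices).
#' @param mask Optional logical array of `dims` restricting analysis.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, dims, subject_id, tissue = "GM",
                        affine = diag(4), mask = NULL) {
  dims <- as.integer(dims)
  if (!is.matrix(data) || ncol(data) != prod(dims))
    stop("data must be an n_subjects x prod(dims) matrix", call. = FALSE)
  if (nrow(data) != length(subject_id))
    stop("subject_id length must match the number of rows", call. = FALSE)
  if (any(data < 0))
    stop("tissue densities must be non-negative", call. = FALSE)
  if (!is.null(mask) && !identical(dim(mask), dims))
    stop("mask dimensions must match grid dimensions", call. = FALSE)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  structure(list(data = data, dims = dims,
                 subject_id = as.character(subject_id),
                 tissue = match.arg(tissue, c("GM", "WM")),
                 affine = affine, mask = mask),
            class = "voxel_stack")
}

#' Extract one subject's map as a 3-D array
#' @param stack A [voxel_stack] object.
#' @param subject Subject id or row index.
#' @return 3-D numeric array.
#' @export
stack_array <- function(stack, subject) {
  i <- if (is.character(subject)) match(subject, stack$subject_id)
       else as.integer(subject)
  if (is.na(i) || i < 1 || i > nrow(stack$data))
    stop("unknown subject: ", subject, call. = FALSE)
  array(stack$data[i, ], stack$dims)
}

#' Map voxel indices (1-based) to mm coordinates through the affine
#' @param affine 4x4 voxel-to-mm affine over 0-based indices.
#' @param ijk Matrix (or vector) of 1-based voxel indices, one row per voxel.
#' @return Matrix of mm coordinates, one row per voxel.
#' @export
voxel_to_mm <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1)          # internal indices are 1-based; affine is 0-based
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat(sprintf("Voxel map stack: %d subjects, %s grid (%s), tissue %s\n",
              nrow(x$data), paste(x$dims, collapse = "x"),
              if (is.null(x$mask)) "no mask"
              else sprintf("%d masked-in voxels", sum(x$mask)),
              x$tissue))
  invisible(x)
}
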