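# Max-cluster-size permutation test: the multiplicity-adjusted p-value of
# each observed suprathreshold cluster is the proportion of permutations
# whose largest suprathreshold component is at least as large.

#' Build the max-cluster-size permutation null
#'
#' For each of `n_perm` repetitions, the subject-to-image assignment is
#' permuted uniformly at random (images shuffled across subjects, the
#' covariate and engagement data kept fixed), the voxel-wise GLM is
#' refit, and the size of the largest suprathreshold connected component
#' is recorded.  No minimum-size filter is applied to the null maxima
#' (filtering the null would be anti-conservative); a permutation with
#' no suprathreshold voxel contributes 0.
#'
#' @inheritParams fit_voxel_glm
#' @param n_perm Number of permutations (default 250).
#' @param threshold Voxel-level t threshold.
#' @param connectivity 6, 18 or 26.
#' @param seed Integer seed; the null is reproducible given the seed.
#' @param mask Optional logical array (defaults as in [fit_voxel_glm()]).
#' @return A `null_distribution` object: list with `max_sizes`
#'   (integer vector of length `n_perm`), `n_perm`, `threshold`,
#'   `connectivity`, `seed`.
#' @export
build_null_distribution <- function(stack, design, engagement,
                                    n_perm = 250, threshold = 3.11,
                                    connectivity = 26, seed = 1L,
                                    mask = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  fit <- fit_voxel_glm(stack, design, engagement, mask = mask)
  midx <- which(fit$mask)
  Y <- stack$data[match(rownames(design), stack$subject_id), midx,
                  drop = FALSE]
  n <- nrow(Y)
  d <- fit$dims
  max_sizes <- integer(n_perm)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    st <- voxel_t_stats(fit$qrX, fit$u_focal, Y[perm, , drop = FALSE],
                        fit$df)
    supra <- array(FALSE, d)
    supra[midx[st$t > threshold]] <- TRUE
    if (!any(supra)) {
      max_sizes[b] <- 0L
      next
    }
    labels <- label_components_3d(supra, connectivity)
    max_sizes[b] <- max(tabulate(labels[labels > 0]))
  }
  structure(list(max_sizes = max_sizes, n_perm = as.integer(n_perm),
                 threshold = threshold, connectivity = connectivity,
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' Permutation p-value of a cluster
#'
#' `p = #\{b : \max_b \ge size\} / n_perm`: the proportion of
#' permutations whose largest suprathreshold component was at least as
#' large as the observed cluster.  A plain proportion is reported (no
#' +1 smoothing), so p = 0 is possible.  Monotone non-increasing in the
#' cluster size for a fixed null.
#'
#' @param size Observed cluster size(s) in voxels (numeric vector), or a
#'   `cluster_set`, in which case the `size` column is used.
#' @param null A `null_distribution` from [build_null_distribution()].
#' @return Numeric p-value(s) in \[0, 1\].
#' @export
cluster_pvalue <- function(size, null) {
  if (inherits(size, "cluster_set")) size <- size$size
  if (null$n_perm < 1) stop("empty null distribution", call. = FALSE)
  vapply(size, function(s) sum(null$max_sizes >= s) / null$n_perm,
         numeric(1))
}

#' Run the voxel-wise pipeline end to end
#'
#' Fits the voxel-wise GLM, extracts suprathreshold clusters, builds the
#' max-cluster-size permutation null, and fills each observed cluster's
#' adjusted p-value.  Run once per tissue class (GM and WM maps are
#' analysed separately).
#'
#' @inheritParams build_null_distribution
#' @param min_size Minimum extent of *reported* clusters (the null maxima
#'   are not size-filtered).
#' @return A `vbm_result` list: `stat_map`, `clusters` (with `cluster_p`
#'   filled), `null`.
#' @export
run_vbm_pipeline <- function(stack, design, engagement,
                             threshold = 3.11, min_size = 100,
                             connectivity = 26, n_perm = 250,
                             seed = 1L, mask = NULL) {
  map <- fit_voxel_glm(stack, design, engagement, mask = mask)
  clusters <- extract_clusters(map, threshold = threshold,
                               min_size = min_size,
                               connectivity = connectivity)
  null <- build_null_distribution(stack, design, engagement,
                                  n_perm = n_perm, threshold = threshold,
                                  connectivity = connectivity,
                                  seed = seed, mask = mask)
  clusters$cluster_p <- if (nrow(clusters) > 0)
    cluster_pvalue(clusters, null) else numeric(0)
  map$qrX <- NULL  # drop fitting internals from the returned object
  structure(list(stat_map = map, clusters = clusters, null = null),
            class = "vbm_result")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "Max-cluster-size permutation null: %d repetitions (t > %.2f, %d-conn)\n",
    x$n_perm, x$threshold, x$connectivity))
  print(summary(x$max_sizes))
  invisible(x)
}

#' @export
print.vbm_result <- function(x, ...) {
  print(x$stat_map)
  print(x$clusters)
  invisible(x)
}
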