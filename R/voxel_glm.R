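# Voxel-wise GLM: one shared QR projection applied across all voxels,
# mathematically identical to fitting per-voxel OLS of voxel volume on
# the covariates plus engagement.

# t-statistics for the focal (last) design column at every column of Y.
# Returns the t vector plus diagnostic counts; used by both the observed
# fit and the permutation loop.
voxel_t_stats <- function(qrX, u_focal, Y, df, sentinel = 1e6) {
  beta <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  rss <- colSums(resid^2)
  b <- beta[nrow(beta), ]
  scale_y <- colSums(Y^2)
  zero_var <- apply(Y, 2, stats::var) == 0
  perfect <- !zero_var & rss <= 1e-12 * pmax(scale_y, 1)
  se <- sqrt(pmax(rss, 0) / df * u_focal)
  t <- ifelse(se > 0, b / se, 0)
  t[perfect] <- sign(beta[nrow(beta), perfect]) * sentinel
  t[zero_var] <- 0
  list(t = t, n_zero_variance = sum(zero_var), n_perfect_fit = sum(perfect))
}

#' Fit the voxel-wise GLM t-map
#'
#' At every voxel inside the analysis mask, fits OLS of the voxel's
#' tissue density on the covariate design plus the engagement score and
#' returns the t-statistic of the engagement coefficient.  The fit is
#' implemented as one shared QR projection applied across voxels, which
#' is mathematically identical to per-voxel regression.  Voxels with
#' zero variance across subjects get `t = 0` and are counted; voxels fit
#' perfectly (zero residual with a nonzero coefficient) get a large
#' signed sentinel t and a warning, rather than failing the whole map.
#'
#' @param stack A [voxel_stack] of aligned subject maps.
#' @param design Covariate matrix from [build_design_matrix()]; row names
#'   must match `stack$subject_id` order (they are checked).
#' @param engagement Engagement scores (named vector or aligned vector).
#' @param mask Optional logical array; defaults to the stack's mask, or
#'   to all voxels with nonzero variance across subjects.
#' @return A `stat_map` object: list with `t` (3-D array, 0 outside the
#'   mask), `df` (residual degrees of freedom), `mask`, `affine`,
#'   `dims`, and the zero-variance / perfect-fit counts.
#' @export
fit_voxel_glm <- function(stack, design, engagement, mask = NULL) {
  ids <- rownames(design)
  if (!identical(as.character(ids), stack$subject_id)) {
    if (!setequal(ids, stack$subject_id))
      stop("design and stack cover different subjects", call. = FALSE)
    # reorder maps to the design's subject order
    stack$data <- stack$data[match(ids, stack$subject_id), , drop = FALSE]
    stack$subject_id <- as.character(ids)
  }
  eng <- align_engagement(engagement, ids)
  if (stats::sd(eng) == 0)
    stop("zero-variance predictor: engagement is constant", call. = FALSE)
  X <- cbind(design, engagement = eng)
  n <- nrow(X)
  if (n <= ncol(X) + 1)
    stop("need more subjects than design columns", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  df <- n - ncol(X)
  u_focal <- focal_variance_factor(X)

  if (is.null(mask)) mask <- stack$mask
  if (is.null(mask)) {
    v <- matrixStats_colVars(stack$data)
    mask <- array(v > 0, stack$dims)
  }
  midx <- which(as.logical(mask))
  tvec <- rep(0, prod(stack$dims))
  stats <- voxel_t_stats(qrX, u_focal, stack$data[, midx, drop = FALSE], df)
  tvec[midx] <- stats$t
  if (stats$n_perfect_fit > 0)
    warning(stats$n_perfect_fit,
            " voxel(s) fit perfectly; sentinel t reported", call. = FALSE)
  structure(list(t = array(tvec, stack$dims), df = df,
                 mask = array(as.logical(mask), stack$dims),
                 affine = stack$affine, dims = stack$dims,
                 tissue = stack$tissue,
                 n_zero_variance = stats$n_zero_variance,
                 n_perfect_fit = stats$n_perfect_fit,
                 qrX = qrX, u_focal = u_focal),
            class = "stat_map")
}

# [(X'X)^{-1}]_{kk} for the last column, via the QR factor.
focal_variance_factor <- function(X) {
  XtXinv <- chol2inv(qr.R(qr(X)))
  XtXinv[ncol(X), ncol(X)]
}

# colVars without extra dependencies
matrixStats_colVars <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  (colSums(M^2) - n * mu^2) / (n - 1)
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  g <- as.matrix(g[keep, ])
  # half-space of offsets: each undirected neighbor pair generated once
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))),
    , drop = FALSE]
}

#' Label connected components of a 3-D binary grid
#'
#' Connected-component labeling of the `TRUE` voxels of a 3-D logical
#' array under 6- (face), 18- (face+edge) or 26- (face+edge+vertex)
#' neighbor connectivity.  Implemented by building the neighbor edge
#' list over in-mask voxels and extracting graph components.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same dimensions: 0 outside components,
#'   component labels 1..k inside (label order arbitrary).
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be a 3-D array", call. = FALSE)
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- pos[lin] > 0L
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[lin][hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  membership <- igraph::components(g)$membership
  labels[idx] <- as.integer(membership)
  labels
}

#' Extract suprathreshold clusters from a t-map
#'
#' Thresholds the t-map (one-sided, positive contrast), labels connected
#' components, and reports every component of at least `min_size` voxels
#' as a cluster with its size, peak t, one-sided uncorrected p of the
#' peak, and affine-transformed centroid (mm), sorted by size
#' descending.  The adjusted `cluster_p` column is `NA` until filled by
#' the permutation test ([cluster_pvalue()] / [run_vbm_pipeline()]).
#'
#' @param map A `stat_map` from [fit_voxel_glm()].
#' @param threshold Voxel-level t threshold (default 3.11, the one-sided
#'   p = 0.001 critical value at the reference design's residual df).
#' @param min_size Minimum cluster extent in voxels (default 100).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `cluster_set` data frame (`cluster_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `peak_t`, `peak_p`, `size`, `cluster_p`) with member voxel
#'   indices in attribute `"voxels"` and the extraction parameters in
#'   attributes.
#' @export
extract_clusters <- function(map, threshold = 3.11, min_size = 100,
                             connectivity = 26) {
  stopifnot(!is.na(threshold), min_size >= 1)  # +Inf allowed: empty set
  supra <- map$mask & map$t > threshold
  labels <- label_components_3d(supra, connectivity)
  empty <- data.frame(cluster_id = integer(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      peak_t = numeric(0), peak_p = numeric(0),
                      size = integer(0), cluster_p = numeric(0))
  k <- max(labels)
  rows <- list(); voxels <- list()
  if (k > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = k)
    keep <- which(sizes >= min_size)
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) {
      vox <- which(labels == keep[i])
      tv <- map$t[vox]
      peak <- max(tv)
      ctr <- colMeans(arrayInd(vox, map$dims))
      mm <- voxel_to_mm(map$affine, ctr)
      rows[[i]] <- data.frame(
        cluster_id = i, x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
        peak_t = peak,
        peak_p = stats::pt(peak, map$df, lower.tail = FALSE),
        size = length(vox), cluster_p = NA_real_
      )
      voxels[[i]] <- vox
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  structure(out, voxels = voxels, threshold = threshold,
            min_size = min_size, connectivity = connectivity,
            df = map$df, tissue = map$tissue,
            class = c("cluster_set", "data.frame"))
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "Voxel-wise t-map: %s grid, df = %d, %d masked-in voxels\n",
    paste(x$dims, collapse = "x"), x$df, sum(x$mask)))
  if (x$n_zero_variance > 0)
    cat("  zero-variance voxels set to t = 0:", x$n_zero_variance, "\n")
  invisible(x)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "%d suprathreshold cluster(s) (t > %.2f, >= %d voxels, %d-connectivity)\n",
    nrow(x), attr(x, "threshold"), attr(x, "min_size"),
    attr(x, "connectivity")))
  if (nrow(x) > 0) print(as.data.frame(round(x, 3)), row.names = FALSE)
  invisible(x)
}
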