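# Independent oracles used across the suite.

# Classical OLS by explicit normal equations: (X'X)^{-1} X'y with
# homoskedastic SEs.  Deliberately distinct from the package's QR/lm route.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  b <- as.numeric(XtXinv %*% t(X) %*% y)
  res <- y - as.numeric(X %*% b)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXinv))
  t <- b / se
  list(b = stats::setNames(b, colnames(X)), se = stats::setNames(se, colnames(X)),
       t = stats::setNames(t, colnames(X)),
       p = stats::setNames(2 * stats::pt(abs(t), df, lower.tail = FALSE),
                           colnames(X)),
       df = df)
}

# Exhaustive breadth-first flood fill over a 3-D logical array.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- as.matrix(offs[switch(as.character(connectivity),
                                "6" = ord == 1, "18" = ord <= 2,
                                "26" = ord <= 3), ])
  labels <- array(0L, d)
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- lab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# Two labelings agree up to label permutation.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  idx <- which(a > 0)
  if (length(idx) == 0) return(TRUE)
  key <- paste(a[idx], b[idx])
  length(unique(key)) == length(unique(a[idx])) &&
    length(unique(key)) == length(unique(b[idx]))
}

# Small standard fixture: cohort + design + named engagement scores.
make_fixture <- function(n = 60, seed = 101, ...) {
  cfg <- sim_config(n_subjects = n, seed = seed, ...)
  cohort <- simulate_cohort(cfg)
  design <- suppressWarnings(build_design_matrix(cohort))
  list(cfg = cfg, cohort = cohort, design = design,
       engagement = stats::setNames(cohort$engagement, cohort$subject_id))
}
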