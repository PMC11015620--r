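#' Niche overlap indices and equivalency test
#'
#' Schoener's D = 1 - 0.5 * sum |z1 - z2| and Warren's standardized
#' Hellinger-based I = 1 - 0.5 * sum (sqrt(z1) - sqrt(z2))^2 on occurrence
#' density grids (renormalized to sum to one). When occurrence points are
#' supplied, a niche-equivalency permutation test pools the points,
#' reassigns group labels at random, rebuilds kernel densities on the
#' common grid, and recomputes D; the p-value is two-sided with the
#' (1 + count) / (1 + n_perm) convention.
#'
#' @param dens1,dens2 nonnegative density matrices on a common grid.
#' @param points1,points2 optional n x 2 matrices of occurrence coordinates
#'   (columns x, y) enabling the equivalency test.
#' @param n_perm permutations for the equivalency test (default 100).
#' @param seed RNG seed.
#' @param grid_n kernel-density grid size used when rebuilding densities.
#' @return list with \code{D}, \code{I}, and (when points are given)
#'   \code{p_equivalency} and the permuted \code{D_null} values.
#' @export
niche_overlap <- function(dens1, dens2, points1 = NULL, points2 = NULL,
                          n_perm = 100, seed = 1, grid_n = 50) {
  z1 <- as.matrix(dens1); z2 <- as.matrix(dens2)
  stopifnot(identical(dim(z1), dim(z2)))
  if (any(z1 < 0) || any(z2 < 0)) stop("densities must be nonnegative")
  if (sum(z1) == 0 || sum(z2) == 0) stop("all-zero density grid")
  z1 <- z1 / sum(z1); z2 <- z2 / sum(z2)
  D <- 1 - 0.5 * sum(abs(z1 - z2))
  I <- 1 - 0.5 * sum((sqrt(z1) - sqrt(z2))^2)
  out <- list(D = D, I = I)
  if (!is.null(points1) && !is.null(points2)) {
    pts <- rbind(as.matrix(points1), as.matrix(points2))
    n1 <- nrow(points1)
    lims <- c(range(pts[, 1]), range(pts[, 2]))
    dens_of <- function(p) {
      k <- MASS::kde2d(p[, 1], p[, 2], n = grid_n, lims = lims)
      k$z / sum(k$z)
    }
    d_obs <- {
      a <- dens_of(pts[seq_len(n1), , drop = FALSE])
      b <- dens_of(pts[-seq_len(n1), , drop = FALSE])
      1 - 0.5 * sum(abs(a - b))
    }
    set.seed(seed)
    d_null <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      idx <- sample.int(nrow(pts), n1)
      a <- dens_of(pts[idx, , drop = FALSE])
      b <- dens_of(pts[-idx, , drop = FALSE])
      d_null[k] <- 1 - 0.5 * sum(abs(a - b))
    }
    p_lo <- (1 + sum(d_null <= d_obs)) / (1 + n_perm)
    p_hi <- (1 + sum(d_null >= d_obs)) / (1 + n_perm)
    out$p_equivalency <- min(1, 2 * min(p_lo, p_hi))
    out$D_observed_points <- d_obs
    out$D_null <- d_null
  }
  out
}

#' Maximum sensitivity + specificity threshold and TSS
#'
#' Scans every unique score as a candidate presence threshold (predicted
#' present when score >= threshold) and returns the one maximizing the true
#' skill statistic TSS = sensitivity + specificity - 1. Ties resolve to the
#' lowest threshold.
#'
#' @param scores numeric suitability scores.
#' @param labels logical or 0/1 presence labels (both classes required).
#' @return list with \code{threshold}, \code{tss}, \code{sensitivity},
#'   \code{specificity}.
#' @export
tss_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  cand <- sort(unique(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  best <- list(tss = -Inf)
  for (th in cand) {
    pred <- scores >= th
    sens <- sum(pred & labels) / n_pos
    spec <- sum(!pred & !labels) / n_neg
    tss <- sens + spec - 1
    if (tss > best$tss + 1e-12) {
      best <- list(threshold = th, tss = tss, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

#' Apply a presence threshold to a climate-grid layer
#'
#' @param grid a \code{\link{climate_grid}}.
#' @param layer layer holding suitability scores.
#' @param threshold presence cutoff (e.g. from \code{\link{tss_threshold}}).
#' @return logical matrix (\code{TRUE} = suitable), respecting the grid mask.
#' @export
binarize_grid <- function(grid, layer, threshold) {
  stopifnot(inherits(grid, "climate_grid"), layer %in% names(grid$layers))
  out <- grid$layers[[layer]] >= threshold
  out & grid$mask
}
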