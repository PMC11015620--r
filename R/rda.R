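#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated (default threshold: the longest minimum-spanning-tree
#' edge), exceedances are replaced by four times the threshold, and the
#' positive-eigenvalue axes of the double-centered matrix are returned
#' (computed with \code{vegan::pcnm}).
#'
#' @param coords data.frame with \code{lat}, \code{lon} (>= 3 sites), or a
#'   precomputed \code{dist_matrix} of kind \code{geo}.
#' @param truncation optional truncation distance (km).
#' @return list with \code{vectors} (sites x axes), \code{values}
#'   (eigenvalues, non-increasing), \code{threshold}, and \code{half}
#'   (the first floor(n_positive / 2) axes, the conventional subset).
#' @export
pcnm_axes <- function(coords, truncation = NULL) {
  if (inherits(coords, "dist_matrix")) {
    D <- stats::as.dist(unclass_dist(coords))
  } else {
    stopifnot(nrow(coords) >= 3)
    D <- stats::as.dist(unclass_dist(build_distances(coords)$geo))
  }
  res <- if (is.null(truncation)) vegan::pcnm(D) else
    vegan::pcnm(D, threshold = truncation)
  vec <- as.matrix(res$vectors)
  vals <- res$values[res$values > 0]
  half_n <- floor(ncol(vec) / 2)
  list(vectors = vec, values = vals[seq_len(ncol(vec))],
       threshold = res$threshold,
       half = vec[, seq_len(max(half_n, 1)), drop = FALSE])
}

#' Three-set partial-RDA variance partitioning
#'
#' Partitions the variance of a multivariate response among three predictor
#' sets by redundancy analysis: adjusted R-squared (Ezekiel) is computed for
#' each of the seven subset models and the pure, pairwise-joint and
#' three-way fractions are obtained by inclusion-exclusion. The full model
#' and each pure fraction are tested by permutation
#' (\code{vegan::anova.cca}; pure fractions via partial RDA with the other
#' two sets as Condition).
#'
#' @param response numeric matrix (rows = sites) — e.g. a genotype dosage
#'   matrix or PCoA axes of a genetic distance.
#' @param set_A,set_B,set_C data.frames/matrices of predictors, rows aligned
#'   with the response.
#' @param n_perm permutations for the significance tests.
#' @param seed RNG seed.
#' @return An object of class \code{variance_partition}: \code{fractions}
#'   (named vector: pure_A, pure_B, pure_C, joint_AB, joint_AC, joint_BC,
#'   joint_ABC, residual), \code{r2_models} (adjusted R-squared of the 7
#'   models), \code{p_full}, \code{p_pure} (named vector).
#' @export
rda_partition <- function(response, set_A, set_B, set_C, n_perm = 999,
                          seed = 1) {
  Y <- as.matrix(response)
  A <- as.data.frame(set_A); B <- as.data.frame(set_B)
  C <- as.data.frame(set_C)
  stopifnot(nrow(A) == nrow(Y), nrow(B) == nrow(Y), nrow(C) == nrow(Y),
            ncol(A) >= 1, ncol(B) >= 1, ncol(C) >= 1)
  names(A) <- paste0("A_", names(A))
  names(B) <- paste0("B_", names(B))
  names(C) <- paste0("C_", names(C))
  dat <- cbind(A, B, C)
  adj <- function(cols) {
    m <- vegan::rda(Y ~ ., data = dat[, cols, drop = FALSE])
    vegan::RsquareAdj(m)$adj.r.squared
  }
  nA <- names(A); nB <- names(B); nC <- names(C)
  r2 <- c(A = adj(nA), B = adj(nB), C = adj(nC),
          AB = adj(c(nA, nB)), AC = adj(c(nA, nC)), BC = adj(c(nB, nC)),
          ABC = adj(c(nA, nB, nC)))
  a <- r2[["ABC"]] - r2[["BC"]]
  b <- r2[["ABC"]] - r2[["AC"]]
  cc <- r2[["ABC"]] - r2[["AB"]]
  d <- r2[["ABC"]] - r2[["C"]] - a - b      # A&B joint, not C
  e <- r2[["ABC"]] - r2[["A"]] - b - cc     # B&C joint, not A
  f <- r2[["ABC"]] - r2[["B"]] - a - cc     # A&C joint, not B
  g <- r2[["ABC"]] - a - b - cc - d - e - f
  fractions <- c(pure_A = a, pure_B = b, pure_C = cc,
                 joint_AB = d, joint_BC = e, joint_AC = f,
                 joint_ABC = g, residual = 1 - r2[["ABC"]])
  set.seed(seed)
  full <- vegan::rda(Y ~ ., data = dat)
  p_full <- vegan::anova.cca(full, permutations = n_perm)$`Pr(>F)`[1]
  pure_p <- function(keep, cond) {
    fm <- stats::as.formula(paste(
      "Y ~", paste(keep, collapse = "+"),
      "+ Condition(", paste(cond, collapse = "+"), ")"))
    m <- vegan::rda(fm, data = dat)
    vegan::anova.cca(m, permutations = n_perm)$`Pr(>F)`[1]
  }
  p_pure <- c(pure_A = pure_p(nA, c(nB, nC)),
              pure_B = pure_p(nB, c(nA, nC)),
              pure_C = pure_p(nC, c(nA, nB)))
  structure(list(fractions = fractions, r2_models = r2,
                 p_full = p_full, p_pure = p_pure),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Partial-RDA variance partition (adjusted R^2)\n")
  print(round(x$fractions, 4))
  cat(sprintf("full-model p = %.4g; pure-fraction p: %s\n", x$p_full,
              paste(sprintf("%s=%.3g", names(x$p_pure), x$p_pure),
                    collapse = ", ")))
  invisible(x)
}
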