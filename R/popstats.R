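#' Genotype PCA
#'
#' Principal component analysis of the dosage matrix after per-locus mean
#' imputation of missing genotypes and column centering (no scaling);
#' monomorphic columns contribute nothing. Scores come from the singular
#' value decomposition.
#'
#' @param g a \code{\link{genotype_matrix}} or dosage matrix.
#' @param n_components number of components to return.
#' @return list with \code{scores} (individuals x components),
#'   \code{loadings} (loci x components), \code{explained} (variance
#'   fractions, non-increasing, summing to at most 1).
#' @export
genotype_pca <- function(g, n_components = 10) {
  m <- impute_mean(g)
  m <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(m) < 1e-12)) stop("all loci monomorphic; PCA undefined")
  k <- min(n_components, nrow(m) - 1, ncol(m))
  sv <- svd(m, nu = k, nv = k)
  ev <- sv$d^2
  list(scores = sv$u %*% diag(sv$d[seq_len(k)], k, k),
       loadings = sv$v,
       explained = (ev / sum(ev))[seq_len(k)])
}

#' Nei (1972) standard genetic distance
#'
#' D = -ln(J_xy / sqrt(J_x J_y)) with J the mean over loci of the summed
#' squared allele frequencies (biallelic: p^2 + (1-p)^2, cross term
#' p_x p_y + (1-p_x)(1-p_y)). Pairs with no shared alleles at any locus have
#' infinite distance; these are capped at \code{cap} and flagged.
#'
#' @param pop_freqs populations x loci matrix of alternate-allele
#'   frequencies (e.g. from \code{\link{allele_freqs}(g, by_pop = TRUE)}).
#' @param cap value substituted for infinite distances.
#' @return A symmetric \code{dist_matrix} (see \code{\link{dist_matrix}})
#'   with attribute \code{"capped"}: logical matrix of capped entries.
#' @export
nei_distance <- function(pop_freqs, cap = 50) {
  p <- as.matrix(pop_freqs)
  r <- nrow(p)
  labs <- rownames(p)
  if (is.null(labs)) labs <- paste0("pop", seq_len(r))
  D <- matrix(0, r, r, dimnames = list(labs, labs))
  capped <- matrix(FALSE, r, r)
  J_self <- rowMeans(p^2 + (1 - p)^2, na.rm = TRUE)
  for (i in seq_len(r - 1)) {
    for (j in seq((i + 1), r)) {
      ok <- !is.na(p[i, ]) & !is.na(p[j, ])
      Jxy <- mean(p[i, ok] * p[j, ok] + (1 - p[i, ok]) * (1 - p[j, ok]))
      if (Jxy <= 0) {
        D[i, j] <- D[j, i] <- cap
        capped[i, j] <- capped[j, i] <- TRUE
      } else {
        D[i, j] <- D[j, i] <- -log(Jxy / sqrt(J_self[i] * J_self[j]))
      }
    }
  }
  out <- dist_matrix(D, kind = "genetic")
  attr(out, "capped") <- capped
  out
}

#' Neighbor joining
#'
#' Saitou-Nei neighbor joining with the standard Q-matrix. Q-matrix ties are
#' broken deterministically in favor of the lowest taxon-index pair.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' adjacent branch of the joined pair.
#'
#' @param d symmetric distance matrix with labels (matrix or
#'   \code{dist_matrix}), at least 3 taxa, finite entries.
#' @return Newick string (unrooted, with branch lengths).
#' @export
neighbor_joining <- function(d) {
  D <- unclass_dist(d)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(!is.finite(D))) stop("distances must be finite")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nodes <- as.list(labs)          # Newick fragment per active node
  repeat {
    m <- nrow(D)
    if (m == 2) {
      nw <- sprintf("(%s:%.10g,%s);", nodes[[1]], D[1, 2], nodes[[2]])
      return(nw)
    }
    if (m == 3) {
      # three-point formulas close the star exactly
      v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
      v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
      v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
      v <- pmax(c(v1, v2, v3), 0)
      return(sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                     nodes[[1]], v[1], nodes[[2]], v[2], nodes[[3]], v[3]))
    }
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    # clamp negatives, shifting the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vj <- max(vj, 0)
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], vi, nodes[[j]], vj)
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    nodes <- c(nodes[others], newnode)
  }
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' Gower-centered partition of squared distances, permutation p-value with
#' the (1 + count) / (1 + n_perm) convention. Computed with
#' \code{vegan::adonis2}.
#'
#' @param d distance matrix (matrix or \code{dist_matrix}) over individuals.
#' @param groups factor of group memberships (each group of size >= 2).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with \code{F}, \code{p}, \code{r2}, and the underlying
#'   \code{vegan} table.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  D <- unclass_dist(d)
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  set.seed(seed)
  df <- data.frame(grp = groups)
  tab <- vegan::adonis2(stats::as.dist(D) ~ grp, data = df,
                        permutations = n_perm)
  list(F = tab$F[1], p = tab$`Pr(>F)`[1], r2 = tab$R2[1], table = tab)
}

#' Project the folded site frequency spectrum
#'
#' Hypergeometric projection: each locus with minor-allele count d among n
#' sampled chromosomes contributes its expected distribution over counts at
#' a smaller projected size m, then the spectrum is folded. Mass landing on
#' the monomorphic classes after projection is reported separately, so total
#' locus mass is conserved.
#'
#' @param allele_counts per-locus count of the focal (minor) allele.
#' @param sample_sizes per-locus number of successfully sampled chromosomes
#'   (2 x genotyped individuals).
#' @param n_projected projected number of chromosomes (>= 2); loci with
#'   fewer sampled chromosomes than this are dropped (counted in
#'   \code{n_dropped}).
#' @return list with \code{sfs} (named vector over folded classes 1 ..
#'   floor(m/2)), \code{monomorphic} (projected mass in the 0 class),
#'   \code{n_dropped}.
#' @export
project_sfs <- function(allele_counts, sample_sizes, n_projected) {
  if (n_projected < 2) stop("n_projected must be >= 2")
  m <- as.integer(n_projected)
  stopifnot(length(allele_counts) == length(sample_sizes))
  keep <- sample_sizes >= m
  ac <- allele_counts[keep]; ss <- sample_sizes[keep]
  classes <- 0:m
  spec <- numeric(m + 1)
  for (l in seq_along(ac)) {
    w <- stats::dhyper(classes, ac[l], ss[l] - ac[l], m)
    spec <- spec + w
  }
  # fold: class k pools with m - k
  half <- floor(m / 2)
  folded <- numeric(half)
  for (k in seq_len(half)) {
    folded[k] <- spec[k + 1] + if (m - k != k) spec[m - k + 1] else 0
  }
  mono <- spec[1] + spec[m + 1]
  names(folded) <- as.character(seq_len(half))
  list(sfs = folded, monomorphic = mono, n_dropped = sum(!keep))
}
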