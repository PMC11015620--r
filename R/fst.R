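#' Weir-Cockerham F_ST
#'
#' Per-locus theta variance components (a: among populations, b: among
#' individuals within populations, c: within individuals) from genotype
#' counts, with the multilocus estimate as the ratio of sums
#' sum(a) / sum(a + b + c). Also returns the pairwise population matrix
#' (each entry computed on the two populations alone) and Weir-Goudet
#' population-specific estimates. Missing genotypes are excluded per locus
#' per population; loci where the components are undefined (fewer than two
#' populations with data, or zero total variance) are skipped and counted.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param grouping population label per individual (default: the labels in
#'   \code{g}).
#' @param pairwise compute the pairwise matrix (quadratic in populations).
#' @return An object of class \code{fst_result}: \code{per_locus} (data.frame
#'   with components a, b, c and the per-locus estimate), \code{multilocus},
#'   \code{mean_of_ratios}, \code{pairwise} (matrix or NULL),
#'   \code{pop_specific} (Weir-Goudet beta per population), and
#'   \code{n_skipped}.
#' @export
weir_cockerham_fst <- function(g, grouping = NULL, pairwise = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(grouping)) grouping <- g$individuals$pop
  grouping <- as.character(grouping)
  pops <- unique(grouping)
  if (length(pops) < 2) stop("need at least two populations")
  comp <- wc_components(g$geno, grouping)
  per_locus <- data.frame(locus = colnames(g$geno), a = comp$a, b = comp$b,
                          c = comp$c,
                          fst = comp$a / (comp$a + comp$b + comp$c))
  ok <- is.finite(per_locus$fst)
  multilocus <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  pw <- NULL
  if (pairwise) {
    pw <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in seq((i + 1), length(pops))) {
        rows <- grouping %in% pops[c(i, j)]
        cc <- wc_components(g$geno[rows, , drop = FALSE], grouping[rows])
        tot <- cc$a + cc$b + cc$c
        okij <- is.finite(tot) & tot > 0
        pw[i, j] <- pw[j, i] <- sum(cc$a[okij]) / sum(tot[okij])
      }
    }
  }
  structure(list(per_locus = per_locus, multilocus = multilocus,
                 mean_of_ratios = mean(per_locus$fst[ok]),
                 pairwise = pw,
                 pop_specific = weir_goudet_beta(g$geno, grouping),
                 n_skipped = sum(!ok)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST: multilocus (ratio of sums) = %.4f\n",
              x$multilocus))
  cat(sprintf("  mean of per-locus ratios = %.4f; %d loci skipped\n",
              x$mean_of_ratios, x$n_skipped))
  if (!is.null(x$pairwise)) {
    cat(sprintf("  pairwise matrix over %d populations attached\n",
                nrow(x$pairwise)))
  }
  invisible(x)
}

# Weir & Cockerham (1984) theta variance components per locus, from diploid
# dosages. Vectorized over loci.
wc_components <- function(geno, grouping) {
  pops <- unique(grouping)
  r_all <- length(pops)
  L <- ncol(geno)
  n <- matrix(0, r_all, L)      # genotyped individuals per pop per locus
  p <- matrix(0, r_all, L)      # alt allele frequency
  h <- matrix(0, r_all, L)      # observed heterozygote proportion
  for (k in seq_len(r_all)) {
    sub <- geno[grouping == pops[k], , drop = FALSE]
    n[k, ] <- colSums(!is.na(sub))
    p[k, ] <- colSums(sub, na.rm = TRUE) / (2 * pmax(n[k, ], 1))
    h[k, ] <- colSums(sub == 1, na.rm = TRUE) / pmax(n[k, ], 1)
  }
  use <- n > 0
  r <- colSums(use)                      # populations with data at locus
  nsum <- colSums(n)
  nbar <- nsum / r
  nc <- (nsum - colSums(n^2) / nsum) / (r - 1)
  pbar <- colSums(n * p) / nsum
  s2 <- colSums(n * (p - rep(pbar, each = r_all))^2 * use) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / nsum
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  list(a = a, b = b, c = cc)
}

# Weir & Goudet (2017) population-specific beta from allele-matching
# proportions: beta_i = (M_i - M_B) / (1 - M_B), with M_i the within-
# population matching of distinct allele pairs and M_B the mean
# between-population matching, averaged over loci (ratio of sums).
weir_goudet_beta <- function(geno, grouping) {
  pops <- unique(grouping)
  r <- length(pops)
  L <- ncol(geno)
  Mw_num <- numeric(r); Mw_den <- numeric(r)
  p <- matrix(NA_real_, r, L)
  nn <- matrix(0, r, L)
  for (k in seq_len(r)) {
    sub <- geno[grouping == pops[k], , drop = FALSE]
    nk <- colSums(!is.na(sub))
    pk <- colSums(sub, na.rm = TRUE) / (2 * pmax(nk, 1))
    # matching proportion of two distinct alleles drawn within pop k
    two_n <- 2 * nk
    ssq <- pk^2 + (1 - pk)^2
    match_w <- (two_n * ssq - 1) / (two_n - 1)
    okk <- nk > 0 & two_n > 1
    Mw_num[k] <- sum(match_w[okk]); Mw_den[k] <- sum(okk)
    p[k, ] <- pk; nn[k, ] <- nk
    p[k, nk == 0] <- NA
  }
  Mi <- Mw_num / Mw_den
  Mb_num <- 0; Mb_den <- 0
  for (i in seq_len(r - 1)) {
    for (j in seq((i + 1), r)) {
      ok <- nn[i, ] > 0 & nn[j, ] > 0
      mij <- p[i, ok] * p[j, ok] + (1 - p[i, ok]) * (1 - p[j, ok])
      Mb_num <- Mb_num + sum(mij); Mb_den <- Mb_den + sum(ok)
    }
  }
  Mb <- Mb_num / Mb_den
  beta <- (Mi - Mb) / (1 - Mb)
  names(beta) <- pops
  beta
}

#' Linearized F_ST
#'
#' The isolation-by-distance transform f / (1 - f). Negative estimates pass
#' through (yielding negative values) with a flag attribute.
#'
#' @param f F_ST value(s), each < 1.
#' @return f/(1-f), with attribute \code{"negative_input"} when any f < 0.
#' @export
linearized_fst <- function(f) {
  if (any(f >= 1)) stop("linearized F_ST is infinite at f = 1")
  out <- f / (1 - f)
  if (any(f < 0)) attr(out, "negative_input") <- TRUE
  out
}
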