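#' Mantel test
#'
#' Pearson correlation of the off-diagonal upper triangles of two distance
#' matrices, with significance by jointly permuting the row/column order of
#' the first matrix. One-sided (greater) by default; p uses the
#' (1 + count) / (1 + n_perm) convention. With \code{n_perm = "exact"} all
#' n! relabelings are enumerated (n <= 8) and p = count / n! over the full
#' permutation distribution (the identity included).
#'
#' @param a,b distance matrices with matching labels.
#' @param n_perm number of random permutations, or \code{"exact"}.
#' @param seed RNG seed for random permutations.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return list with \code{r}, \code{p}, \code{n_perm}.
#' @export
mantel <- function(a, b, n_perm = 999, seed = 1,
                   alternative = "greater") {
  A <- unclass_dist(a); B <- unclass_dist(b)
  stopifnot(identical(dim(A), dim(B)))
  va <- A[upper.tri(A)]; vb <- B[upper.tri(B)]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance in a distance triangle; correlation undefined")
  }
  r_obs <- stats::cor(va, vb)
  n <- nrow(A)
  stat <- function(perm) {
    Ap <- A[perm, perm]
    stats::cor(Ap[upper.tri(Ap)], vb)
  }
  if (identical(n_perm, "exact")) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- vapply(perms, stat, numeric(1))
    p <- switch(alternative,
                greater = mean(rs >= r_obs - 1e-12),
                less = mean(rs <= r_obs + 1e-12),
                two.sided = mean(abs(rs) >= abs(r_obs) - 1e-12))
    return(list(r = r_obs, p = p, n_perm = length(perms)))
  }
  set.seed(seed)
  count <- 0L
  for (k in seq_len(n_perm)) {
    rp <- stat(sample.int(n))
    hit <- switch(alternative,
                  greater = rp >= r_obs - 1e-12,
                  less = rp <= r_obs + 1e-12,
                  two.sided = abs(rp) >= abs(r_obs) - 1e-12)
    count <- count + hit
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (s in sub) {
    for (pos in seq_len(n)) {
      out[[k]] <- append(s, n, after = pos - 1L)
      k <- k + 1L
    }
  }
  out
}

#' Partial Mantel test
#'
#' Correlation between the residuals of \code{a ~ control} and
#' \code{b ~ control} over the upper triangle. Significance by permuting
#' the residual matrix of \code{a} (rows and columns jointly) — Legendre's
#' residual-permutation scheme.
#'
#' @inheritParams mantel
#' @param control the conditioning distance matrix.
#' @return list with \code{r}, \code{p}, \code{n_perm}.
#' @export
partial_mantel <- function(a, b, control, n_perm = 999, seed = 1,
                           alternative = "greater") {
  A <- unclass_dist(a); B <- unclass_dist(b); C <- unclass_dist(control)
  stopifnot(identical(dim(A), dim(B)), identical(dim(A), dim(C)))
  n <- nrow(A)
  ut <- upper.tri(A)
  vc <- C[ut]
  resid_mat <- function(M) {
    v <- M[ut]
    if (stats::sd(vc) == 0) {
      r <- v - mean(v)          # vacuous control: plain centering
    } else {
      r <- stats::residuals(stats::lm(v ~ vc))
    }
    R <- matrix(0, n, n)
    R[ut] <- r
    R + t(R)
  }
  Ra <- resid_mat(A); Rb <- resid_mat(B)
  va <- Ra[ut]; vb <- Rb[ut]
  # a response fully explained by the control has no residual signal left:
  # the partial correlation is 0 by convention (not an error)
  tiny_a <- stats::sd(va) <= 1e-12 * max(stats::sd(A[ut]), 1e-300)
  tiny_b <- stats::sd(vb) <= 1e-12 * max(stats::sd(B[ut]), 1e-300)
  if (tiny_a || tiny_b) {
    return(list(r = 0, p = 1, n_perm = n_perm))
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero residual variance; partial correlation undefined")
  }
  r_obs <- stats::cor(va, vb)
  set.seed(seed)
  count <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    Rp <- Ra[perm, perm]
    rp <- stats::cor(Rp[ut], vb)
    hit <- switch(alternative,
                  greater = rp >= r_obs - 1e-12,
                  less = rp <= r_obs + 1e-12,
                  two.sided = abs(rp) >= abs(r_obs) - 1e-12)
    count <- count + hit
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Reciprocal causal modeling
#'
#' For each ordered pair of candidate models (focal f, alternative a) the
#' support entry is r_partial(genetic ~ f | a) − r_partial(genetic ~ a | f).
#' A focal model is fully supported when every off-diagonal entry of its row
#' is positive: it beats each alternative in both reciprocal comparisons.
#'
#' @param genetic genetic distance matrix (response).
#' @param models named list of candidate predictor distance matrices
#'   (>= 1).
#' @param n_perm,seed passed to the underlying partial Mantel statistics
#'   (the support matrix itself uses only the correlations, not p-values).
#' @return list with \code{support} (models x models matrix),
#'   \code{fully_supported} (character vector of model names).
#' @export
rcm <- function(genetic, models, n_perm = 0, seed = 1) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  nm <- names(models)
  S <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  pm_r <- function(f, a) {
    res <- tryCatch(
      partial_mantel(genetic, models[[f]], models[[a]], n_perm = 0),
      error = function(e) list(r = NA_real_))
    res$r
  }
  for (f in nm) {
    for (a in nm) {
      if (f == a) next
      S[f, a] <- pm_r(f, a) - pm_r(a, f)
    }
  }
  # a focal model is fully supported iff all off-diagonal entries > 0
  full <- nm[vapply(seq_along(nm), function(i) {
    all(S[i, -i] > 0)
  }, logical(1))]
  if (length(nm) == 1) full <- character(0)
  list(support = S, fully_supported = full)
}
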