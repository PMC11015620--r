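#' Ridge latent factor mixed model association scan
#'
#' Per-locus association between genotype dosage and environmental
#' variables while K latent factors absorb population structure. Missing
#' genotypes are mean-imputed and loci centered. The ridge closed form is
#' used: latent factors are the rank-K left singular vectors of the
#' genotype matrix after shrinking the environmental directions (with a
#' small penalty, the projection onto the orthogonal complement of the
#' environment), and per-locus z-scores come from the joint regression of
#' genotypes on environment plus factors. z-scores are recalibrated by the genomic
#' inflation factor lambda = median(z^2) / qchisq(0.5, 1). With
#' \code{n_runs > 1}, runs refit on bootstrap resamples of individuals and
#' the per-run z-scores are combined by \code{combine} (default median)
#' before calibration.
#'
#' With \code{K = 0} the latent term vanishes and p-values equal ordinary
#' per-locus simple regression (lambda calibration then skipped for a
#' single variable would still apply; it is applied uniformly).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param env data.frame/matrix of environmental variables, rows aligned to
#'   individuals (a \code{pop} column, if present, is used to broadcast
#'   per-population rows to individuals).
#' @param K number of latent factors (0 <= K < min(n_ind, n_loci)).
#' @param ridge_penalty ridge penalty on environmental effects.
#' @param n_runs number of bootstrap runs combined.
#' @param seed RNG seed.
#' @param combine how per-run z-scores are pooled: "median" or "mean".
#' @param calibrate apply genomic-inflation calibration.
#' @return An object of class \code{assoc_result}: \code{z}, \code{p},
#'   \code{q} (loci x variables matrices), \code{effect} (ridge effect
#'   sizes from the final full-data fit), \code{lambda} per variable,
#'   \code{K}, \code{n_runs}, \code{method = "lfmm"}.
#' @export
fit_lfmm <- function(g, env, K = 2, ridge_penalty = 1e-4, n_runs = 1,
                     seed = 1, combine = "median",
                     calibrate = TRUE) {
  Y <- impute_mean(g)
  env <- align_env(env, g)
  X <- as.matrix(env)
  if (any(apply(X, 2, stats::sd) == 0)) {
    bad <- colnames(X)[apply(X, 2, stats::sd) == 0]
    stop("constant environmental variable: ", paste(bad, collapse = ", "))
  }
  n <- nrow(Y); L <- ncol(Y)
  if (K >= min(n, L)) stop("K must be below min(n_individuals, n_loci)")
  X <- scale(X)
  Y <- scale(Y, center = TRUE, scale = FALSE)

  run_z <- function(rows) {
    Yr <- scale(Y[rows, , drop = FALSE], center = TRUE, scale = FALSE)
    Xr <- X[rows, , drop = FALSE]
    fit_zscores(Yr, Xr, K, ridge_penalty)
  }
  set.seed(seed)
  zlist <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rows <- if (r == 1) seq_len(n) else sample.int(n, n, replace = TRUE)
    zlist[[r]] <- run_z(rows)
  }
  z <- if (n_runs == 1) zlist[[1]]$z else {
    arr <- simplify2array(lapply(zlist, `[[`, "z"))
    apply(arr, c(1, 2), if (combine == "mean") mean else stats::median)
  }
  effect <- zlist[[1]]$effect
  lambda <- apply(z, 2, function(zz) {
    stats::median(zz^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  })
  lambda[!is.finite(lambda) | lambda <= 0] <- 1
  p <- z
  df_resid <- nrow(Y) - ncol(X) - 1
  for (j in seq_len(ncol(z))) {
    p[, j] <- if (calibrate) {
      stats::pchisq(z[, j]^2 / lambda[j], df = 1, lower.tail = FALSE)
    } else {
      # exact small-sample reference: matches per-locus OLS t-tests
      2 * stats::pt(-abs(z[, j]), df = df_resid)
    }
  }
  q <- apply(p, 2, stats::p.adjust, method = "BH")
  dimnames(z) <- dimnames(p) <- dimnames(q) <-
    list(colnames(g$geno), colnames(X))
  structure(list(z = z, p = p, q = q, effect = effect, lambda = lambda,
                 K = K, n_runs = n_runs, method = "lfmm"),
            class = "assoc_result")
}

# ridge LFMM closed form: latent factors from the rank-K SVD of the
# genotype matrix after shrinking the environmental directions (with a
# small ridge this is the projection onto the orthogonal complement of X,
# so the factors cannot absorb the environmental signal), then per-locus
# z-scores from the joint regression of Y on [X, U].
fit_zscores <- function(Y, X, K, ridge_penalty) {
  n <- nrow(Y)
  p <- ncol(X)
  sx <- svd(X)
  pos <- sx$d > 1e-10 * max(sx$d)
  Q <- sx$u[, pos, drop = FALSE]
  d2 <- sx$d[pos]^2
  if (K > 0) {
    shrink <- 1 - sqrt(ridge_penalty / (ridge_penalty + d2))
    Ys <- Y - Q %*% (shrink * crossprod(Q, Y))
    sv <- svd(Ys, nu = K, nv = 0)
    U <- sv$u
    Z <- cbind(X, U)
  } else {
    Z <- X
  }
  df <- n - ncol(Z) - 1
  ZtZi <- solve(crossprod(Z))
  Bhat <- ZtZi %*% crossprod(Z, Y)
  res <- Y - Z %*% Bhat
  s2 <- colSums(res^2) / df
  zmat <- t(Bhat[seq_len(p), , drop = FALSE]) /
    sqrt(outer(s2, diag(ZtZi)[seq_len(p)]))
  zmat[!is.finite(zmat)] <- 0     # monomorphic loci carry no evidence
  list(z = zmat, effect = t(Bhat[seq_len(p), , drop = FALSE]))
}

align_env <- function(env, g) {
  env <- as.data.frame(env)
  if (!is.null(env$pop)) {
    rows <- match(g$individuals$pop, env$pop)
    if (anyNA(rows)) stop("environment table missing some populations")
    env <- env[rows, setdiff(names(env), "pop"), drop = FALSE]
  }
  if (nrow(env) != nrow(g$geno)) {
    stop("environment rows do not align with individuals")
  }
  env[vapply(env, is.numeric, logical(1))]
}

#' PCA-outlier scan (pcadapt-style)
#'
#' Regresses each locus on the top-K genotype principal components, forms
#' the loci x K z-score matrix, and computes robust Mahalanobis distances
#' (minimum covariance determinant, support fraction 0.75). p-values come
#' from chi-squared with K degrees of freedom after dividing by the genomic
#' inflation factor.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param K number of principal components (>= 1).
#' @return An \code{assoc_result} with a single pseudo-variable
#'   \code{"mahalanobis"}; \code{stat} holds the raw distances,
#'   \code{zmat} the loci x K z-scores.
#' @export
pcadapt_scan <- function(g, K = 2) {
  Y <- impute_mean(g)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Y)
  if (K < 1) stop("K must be >= 1")
  if (K >= min(dim(Y))) stop("K exceeds available components")
  sv <- svd(Y, nu = K, nv = 0)
  U <- sv$u                                  # orthonormal scores
  Bhat <- crossprod(U, Y)                    # K x loci
  fitted <- U %*% Bhat
  df <- n - K - 1
  s2 <- colSums((Y - fitted)^2) / df
  zmat <- t(Bhat) / sqrt(s2)                 # loci x K
  if (K == 1) {
    # squared standardized loading, robustly scaled; rank order = |z| order
    madv <- stats::mad(zmat, center = 0)
    d2 <- as.vector((zmat / madv)^2)
  } else {
    rob <- MASS::cov.rob(zmat, method = "mcd",
                         quantile.used = floor(0.75 * nrow(zmat)))
    d2 <- stats::mahalanobis(zmat, rob$center, rob$cov)
  }
  gif <- stats::median(d2) / stats::qchisq(0.5, K)
  p <- stats::pchisq(d2 / gif, df = K, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  pm <- cbind(mahalanobis = p)
  rownames(pm) <- colnames(g$geno)
  structure(list(z = cbind(mahalanobis = sqrt(d2)), p = pm,
                 q = cbind(mahalanobis = q), stat = d2, zmat = zmat,
                 lambda = gif, K = K, n_runs = 1, method = "pcadapt"),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s scan: %d loci x %d variable(s), K = %d, runs = %d\n",
              x$method, nrow(x$p), ncol(x$p), x$K, x$n_runs))
  cat(sprintf("  genomic inflation: %s\n",
              paste(sprintf("%.2f", x$lambda), collapse = ", ")))
  cat(sprintf("  loci with q < 0.10 (any variable): %d\n",
              sum(apply(x$q < 0.10, 1, any))))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjusted q-values (monotonicity enforced by the cumulative
#' minimum from the largest p) and the rejection set at a q threshold.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q_threshold rejection threshold on q (default 0.10).
#' @return list with \code{q} and \code{rejected} (indices).
#' @export
bh_fdr <- function(p_values, q_threshold = 0.10) {
  if (length(p_values) == 0) return(list(q = numeric(0), rejected = integer(0)))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, rejected = which(q < q_threshold))
}

#' Outlier set
#'
#' @param ids locus ids flagged.
#' @param method tag: \code{"lfmm"}, \code{"pcadapt"} or \code{"external"}.
#' @param threshold metadata on the threshold used.
#' @return An \code{outlier_set}.
#' @export
outlier_set <- function(ids, method = "external", threshold = NA) {
  structure(list(ids = unique(as.character(ids)), method = method,
                 threshold = threshold), class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set [%s]: %d loci\n", x$method, length(x$ids)))
  invisible(x)
}

#' Intersect GEA hits with F_ST-outlier sets
#'
#' Putatively adaptive loci: significant in the association scan (q below
#' the threshold for any variable) AND present in the union of the
#' F_ST-based outlier sets. Per-locus provenance (significant variables,
#' contributing methods) is retained.
#'
#' @param gea an \code{assoc_result} (from \code{\link{fit_lfmm}}).
#' @param fst_sets list of \code{\link{outlier_set}} objects.
#' @param q_threshold q cutoff for the GEA scan.
#' @return An \code{outlier_set} with attribute \code{"provenance"}
#'   (data.frame: locus, variables, methods).
#' @export
intersect_outliers <- function(gea, fst_sets, q_threshold = 0.10) {
  stopifnot(inherits(gea, "assoc_result"))
  if (inherits(fst_sets, "outlier_set")) fst_sets <- list(fst_sets)
  gea_ids <- rownames(gea$q)[apply(gea$q < q_threshold, 1, any)]
  fst_union <- unique(unlist(lapply(fst_sets, `[[`, "ids")))
  known <- rownames(gea$q)
  if (length(fst_union) > 0 && !any(fst_union %in% known)) {
    stop("F_ST outlier ids share no loci with the association scan")
  }
  ids <- intersect(gea_ids, fst_union)
  prov <- data.frame(locus = ids,
                     variables = vapply(ids, function(l) {
                       paste(colnames(gea$q)[gea$q[l, ] < q_threshold],
                             collapse = ";")
                     }, character(1)),
                     methods = vapply(ids, function(l) {
                       paste(vapply(fst_sets[vapply(fst_sets, function(s)
                         l %in% s$ids, logical(1))], `[[`, character(1),
                         "method"), collapse = ";")
                     }, character(1)))
  out <- outlier_set(ids, method = "intersection", threshold = q_threshold)
  attr(out, "provenance") <- prov
  out
}
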