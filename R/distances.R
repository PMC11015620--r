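#' Labeled symmetric distance matrix
#'
#' Thin wrapper carrying labels and a kind tag (\code{geo},
#' \code{env_climate}, \code{env_soil}, \code{env_topo}, \code{resistance},
#' \code{genetic}, ...). Validates symmetry (to 1e-10 relative), a zero
#' diagonal, and non-negativity.
#'
#' @param m square numeric matrix with dimnames (or labels supplied).
#' @param kind character tag.
#' @param labels optional label vector.
#' @param allow_infinite permit non-finite entries (flagged distances).
#' @return An object of class \code{dist_matrix} (a matrix subclass).
#' @export
dist_matrix <- function(m, kind = "generic", labels = NULL,
                        allow_infinite = FALSE) {
  m <- as.matrix(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("s", seq_len(nrow(m))),
                        paste0("s", seq_len(nrow(m))))
  }
  stopifnot(nrow(m) == ncol(m))
  if (max(abs(m - t(m)), na.rm = TRUE) >
      1e-10 * max(1, max(abs(m), na.rm = TRUE))) {
    stop("matrix is not symmetric")
  }
  m <- (m + t(m)) / 2
  if (any(abs(diag(m)) > 1e-10)) stop("diagonal must be zero")
  diag(m) <- 0
  if (!allow_infinite && any(!is.finite(m))) stop("non-finite distances")
  if (any(m < -1e-12, na.rm = TRUE)) stop("distances must be nonnegative")
  structure(m, class = c("dist_matrix", "matrix"), kind = kind)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix [%s], %d labels\n", attr(x, "kind"), nrow(x)))
  print(unclass_dist(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

# strip the class/attrs, returning a plain base matrix
unclass_dist <- function(d) {
  m <- as.matrix(d)
  attr(m, "kind") <- NULL
  class(m) <- "matrix"
  m
}

upper_tri_vec <- function(d) {
  m <- unclass_dist(d)
  m[upper.tri(m)]
}

#' Geographic and environmental distance matrices
#'
#' Geographic distance is the great-circle (haversine) distance in km,
#' Earth radius 6371 km. Environmental distances are Euclidean on z-scored
#' variables, one matrix per category.
#'
#' @param coords data.frame with \code{lat}, \code{lon} in decimal degrees
#'   (rows = sites, rownames or a \code{pop} column as labels).
#' @param env optional data.frame/matrix of environmental variables aligned
#'   to \code{coords} rows.
#' @param categories optional named list mapping category name to the column
#'   names of \code{env} it contains; default: one category \code{"env"}
#'   with every column.
#' @return named list of \code{\link{dist_matrix}} objects: \code{geo} plus
#'   one per environmental category (kind \code{env_<category>}).
#' @export
build_distances <- function(coords, env = NULL, categories = NULL) {
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  }
  labs <- if (!is.null(coords$pop)) as.character(coords$pop) else
    rownames(coords)
  n <- nrow(coords)
  pts <- cbind(coords$lon, coords$lat)
  geo <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[(i + 1):n, , drop = FALSE],
                                  r = 6371000) / 1000
    geo[i, (i + 1):n] <- d
    geo[(i + 1):n, i] <- d
  }
  out <- list(geo = dist_matrix(geo, kind = "geo", labels = labs))
  if (!is.null(env)) {
    env <- as.matrix(env)
    if (is.null(categories)) categories <- list(env = colnames(env))
    for (cat in names(categories)) {
      z <- scale(env[, categories[[cat]], drop = FALSE])
      z[, attr(z, "scaled:scale") == 0] <- 0   # constant variables
      m <- as.matrix(stats::dist(z))
      out[[cat]] <- dist_matrix(m, kind = paste0("env_", cat), labels = labs)
    }
  }
  out
}

#' Prune collinear environmental variables
#'
#' Two passes: (1) iteratively drop the variable with the highest variance
#' inflation factor until all VIF <= \code{vif_max}; (2) greedily resolve
#' remaining pairs with |Pearson r| > \code{r_max}, keeping the member with
#' the lower mean absolute correlation to everything else. With fewer sites
#' than variables the VIF pass is skipped (correlation-only pruning, with a
#' warning).
#'
#' @param env data.frame or matrix, sites x variables (>= 3 sites, >= 2
#'   variables).
#' @param vif_max VIF ceiling (default 10).
#' @param r_max absolute-correlation ceiling (default 0.8).
#' @return The pruned table, with attribute \code{"prune_report"}: a
#'   data.frame of dropped variables, the rule and the statistic.
#' @export
prune_collinear <- function(env, vif_max = 10, r_max = 0.8) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  e <- as.matrix(env[, num, drop = FALSE])
  stopifnot(ncol(e) >= 2, nrow(e) >= 3)
  dropped <- data.frame(variable = character(), rule = character(),
                        value = numeric())
  keep <- colnames(e)
  vifs_of <- function(cols) {
    R <- stats::cor(e[, cols, drop = FALSE])
    v <- tryCatch(diag(solve(R)), error = function(err) {
      diag(MASS::ginv(R))
    })
    names(v) <- cols
    v
  }
  if (nrow(e) <= length(keep)) {
    warning("fewer sites than variables; skipping VIF pass (correlation-only pruning)")
  } else {
    repeat {
      if (length(keep) < 2) break
      v <- vifs_of(keep)
      if (max(v) <= vif_max && all(is.finite(v))) break
      worst <- names(v)[which.max(ifelse(is.finite(v), v, Inf))]
      dropped <- rbind(dropped, data.frame(variable = worst, rule = "vif",
                                           value = unname(v[worst])))
      keep <- setdiff(keep, worst)
    }
  }
  repeat {
    if (length(keep) < 2) break
    R <- abs(stats::cor(e[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) <= r_max) break
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    mean_r <- colMeans(R)[c(a, b)]
    worse <- if (mean_r[a] >= mean_r[b]) a else b
    dropped <- rbind(dropped, data.frame(variable = worse, rule = "cor",
                                         value = max(R)))
    keep <- setdiff(keep, worse)
  }
  out <- env[, keep, drop = FALSE]
  attr(out, "prune_report") <- dropped
  out
}
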