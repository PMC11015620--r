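#' Gradient-forest model of allelic turnover
#'
#' Fits, per adaptive locus, a random-forest regression of population
#' allele frequency on the environmental variables (\code{n_trees} trees,
#' tree size capped at 2^d terminal nodes with
#' d = ceiling(log2(0.368 * n_individuals / 2))), keeps loci whose
#' out-of-bag R-squared exceeds \code{r2_floor}, and aggregates the forests
#' into per-variable monotone cumulative-importance turnover functions: the
#' split locations of each variable, weighted by locus R-squared times the
#' locus's permutation-importance share of that variable, accumulated along
#' the variable's range. The per-variable overall importance is the
#' turnover function's total mass, normalized so all variables sum to the
#' mean retained R-squared.
#'
#' @param g_adaptive \code{\link{genotype_matrix}} restricted to the
#'   putatively adaptive loci (>= 2 loci).
#' @param env populations x variables table (with \code{pop} column or
#'   rownames = population labels).
#' @param n_trees trees per locus (default 500).
#' @param corr_threshold recorded in the model (band-width correlation
#'   parameter of the reference implementation; the aggregation here does
#'   not use it).
#' @param r2_floor loci with out-of-bag R-squared at or below this are
#'   dropped (default 0).
#' @param seed RNG seed.
#' @return An object of class \code{gf_model}: \code{turnover} (per
#'   variable: sorted split positions and cumulative importance),
#'   \code{importance} (per-variable overall importance), \code{locus_r2},
#'   \code{n_trees}, \code{max_depth}, \code{corr_threshold}.
#' @export
gf_fit <- function(g_adaptive, env, n_trees = 500, corr_threshold = 0.5,
                   r2_floor = 0, seed = 1) {
  stopifnot(inherits(g_adaptive, "genotype_matrix"))
  if (ncol(g_adaptive$geno) < 2) stop("need at least 2 adaptive loci")
  pf <- allele_freqs(g_adaptive, by_pop = TRUE)
  env <- as.data.frame(env)
  if (!is.null(env$pop)) {
    env <- env[match(rownames(pf), env$pop),
               setdiff(names(env), "pop"), drop = FALSE]
  } else {
    env <- env[match(rownames(pf), rownames(env)), , drop = FALSE]
  }
  X <- as.data.frame(env[vapply(env, is.numeric, logical(1))])
  n_ind <- nrow(g_adaptive$geno)
  depth <- max(1, ceiling(log2(0.368 * n_ind / 2)))
  maxnodes <- 2^depth
  set.seed(seed)
  vars <- names(X)
  splits <- stats::setNames(lapply(vars, function(v) {
    list(pos = numeric(0), w = numeric(0))
  }), vars)
  locus_r2 <- numeric(0)
  for (l in colnames(pf)) {
    y <- pf[, l]
    ok <- is.finite(y)
    if (stats::sd(y[ok]) == 0) next
    rf <- suppressWarnings(randomForest::randomForest(
      x = X[ok, , drop = FALSE], y = y[ok], ntree = n_trees,
      maxnodes = min(maxnodes, sum(ok)), importance = TRUE))
    r2 <- 1 - rf$mse[length(rf$mse)] / stats::var(y[ok])
    if (r2 <= r2_floor) next
    locus_r2[l] <- r2
    imp <- randomForest::importance(rf, type = 1)[, 1]
    imp[imp < 0 | !is.finite(imp)] <- 0
    share <- if (sum(imp) > 0) imp / sum(imp) else
      rep(1 / length(vars), length(vars))
    names(share) <- vars
    # collect split points per variable over all trees
    for (t in seq_len(n_trees)) {
      tr <- randomForest::getTree(rf, k = t, labelVar = TRUE)
      sp <- tr[tr$status == -3, c("split var", "split point")]
      if (nrow(sp) == 0) next
      for (v in vars) {
        pts <- sp[sp$`split var` == v, "split point"]
        if (length(pts) == 0) next
        splits[[v]]$pos <- c(splits[[v]]$pos, pts)
        splits[[v]]$w <- c(splits[[v]]$w,
                           rep(r2 * share[[v]], length(pts)))
      }
    }
  }
  if (length(locus_r2) == 0) stop("no predictive loci: all below the R^2 floor")
  # per-variable: normalize split weights so each locus-variable block's
  # mass equals r2 * share, then build cumulative turnover
  turnover <- list()
  importance <- stats::setNames(numeric(length(vars)), vars)
  total_r2 <- mean(locus_r2)
  raw_mass <- vapply(vars, function(v) sum(splits[[v]]$w), numeric(1))
  scale_f <- if (sum(raw_mass) > 0) total_r2 / sum(raw_mass) else 0
  for (v in vars) {
    pos <- splits[[v]]$pos; w <- splits[[v]]$w * scale_f
    if (length(pos) == 0) {
      turnover[[v]] <- list(pos = numeric(0), cum = numeric(0))
      importance[v] <- 0
      next
    }
    o <- order(pos)
    turnover[[v]] <- list(pos = pos[o], cum = cumsum(w[o]))
    importance[v] <- sum(w)
  }
  structure(list(turnover = turnover, importance = importance,
                 locus_r2 = locus_r2, n_trees = n_trees,
                 max_depth = depth, corr_threshold = corr_threshold,
                 variables = vars),
            class = "gf_model")
}

#' @export
print.gf_model <- function(x, ...) {
  cat(sprintf("gradient-forest model: %d loci retained, %d trees/locus, depth cap %d\n",
              length(x$locus_r2), x$n_trees, x$max_depth))
  cat("  variable importance:\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Evaluate turnover functions
#'
#' Maps raw environmental values into cumulative-importance ("genetic
#' composition") space: F_v(x) = summed split importance at positions <= x.
#' Monotone non-decreasing, 0 below the first split, the variable's total
#' importance above the last.
#'
#' @param model a \code{gf_model}.
#' @param newenv data.frame/matrix of raw environmental values (columns
#'   must include the model's variables).
#' @return matrix of transformed values, same rows, one column per model
#'   variable.
#' @export
gf_transform <- function(model, newenv) {
  stopifnot(inherits(model, "gf_model"))
  newenv <- as.data.frame(newenv)
  missing_v <- setdiff(model$variables, names(newenv))
  if (length(missing_v) > 0) {
    stop("variables missing from input: ", paste(missing_v, collapse = ", "))
  }
  out <- matrix(0, nrow(newenv), length(model$variables),
                dimnames = list(NULL, model$variables))
  for (v in model$variables) {
    tv <- model$turnover[[v]]
    if (length(tv$pos) == 0) next
    idx <- findInterval(newenv[[v]], tv$pos)
    out[, v] <- c(0, tv$cum)[idx + 1]
  }
  out
}

#' Gradient-forest genetic offset
#'
#' Offset per unmasked cell: the Euclidean distance between the current and
#' future environments mapped through the turnover functions.
#'
#' @param model a \code{gf_model}.
#' @param current,future \code{\link{climate_grid}}s sharing mask and the
#'   model's variables.
#' @return data.frame: cell, lat, lon, offset; attribute \code{"grid"} is
#'   an offset matrix aligned with the climate grid (NA where masked).
#' @export
gf_offset <- function(model, current, future) {
  stopifnot(inherits(current, "climate_grid"),
            inherits(future, "climate_grid"),
            identical(current$mask, future$mask))
  missing_v <- setdiff(model$variables, names(current$layers))
  if (length(missing_v) > 0) {
    stop("variables missing from the grids: ",
         paste(missing_v, collapse = ", "))
  }
  cur <- grid_cells(current); fut <- grid_cells(future)
  Tc <- gf_transform(model, cur[model$variables])
  Tf <- gf_transform(model, fut[model$variables])
  off <- sqrt(rowSums((Tc - Tf)^2))
  grid <- matrix(NA_real_, nrow(current$mask), ncol(current$mask))
  grid[cur$cell] <- off
  out <- data.frame(cell = cur$cell, lat = cur$lat, lon = cur$lon,
                    offset = off)
  attr(out, "grid") <- grid
  out
}

#' RGB map of gradient-forest genetic composition
#'
#' PCA of the turnover-transformed cell vectors; the first three components
#' are min-max scaled to [0, 1] and returned as red, green, blue channels.
#' With fewer than three effective dimensions the remaining channels are
#' zero-padded with a warning.
#'
#' @param model a \code{gf_model}.
#' @param grid a \code{\link{climate_grid}}.
#' @return data.frame: cell, lat, lon, r, g, b (all channels in [0, 1]);
#'   attribute \code{"scores"} holds the raw PC scores.
#' @export
gf_rgb_map <- function(model, grid) {
  cells <- grid_cells(grid)
  Tm <- gf_transform(model, cells[model$variables])
  Tc <- scale(Tm, center = TRUE, scale = FALSE)
  sv <- svd(Tc)
  eff <- sum(sv$d > 1e-10 * max(sv$d, 1e-300))
  if (eff < 3) warning("fewer than 3 effective dimensions; zero-padding channels")
  k <- min(3, ncol(Tc))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  chan <- matrix(0, nrow(Tc), 3)
  for (j in seq_len(min(3, eff, k))) {
    rng <- range(scores[, j])
    chan[, j] <- if (diff(rng) > 0) (scores[, j] - rng[1]) / diff(rng) else 0.5
  }
  out <- data.frame(cell = cells$cell, lat = cells$lat, lon = cells$lon,
                    r = chan[, 1], g = chan[, 2], b = chan[, 3])
  attr(out, "scores") <- scores
  out
}
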