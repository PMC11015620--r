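#' I-spline basis
#'
#' Monotone (integrated M-spline) basis of order 2 on the range of
#' \code{x}, with interior knots at quantiles. Each basis function rises
#' from 0 at the lower boundary to 1 at the upper boundary; any
#' non-negative combination is non-decreasing.
#'
#' @param x numeric vector of raw values.
#' @param n_splines number of basis functions (>= 2, default 3: knots at
#'   min / median / max).
#' @param knots optional explicit boundary+interior knots (length
#'   \code{n_splines}), e.g. \code{c(min, median, max)} for 3 splines.
#' @return list with \code{basis} (length(x) x n_splines matrix) and
#'   \code{knots}; evaluate at new values with \code{\link{ispline_eval}}.
#' @export
ispline_basis <- function(x, n_splines = 3, knots = NULL) {
  if (is.null(knots)) {
    probs <- seq(0, 1, length.out = n_splines)
    knots <- unname(stats::quantile(x, probs, na.rm = TRUE))
  }
  stopifnot(length(knots) == n_splines)
  list(basis = ispline_eval(x, knots), knots = knots)
}

#' @rdname ispline_basis
#' @param values numeric values at which to evaluate the basis.
#' @export
ispline_eval <- function(values, knots) {
  k <- 2L                                  # quadratic I-splines (order 2)
  n <- length(knots)
  if (knots[n] <= knots[1]) {              # degenerate (constant) variable
    return(matrix(0, length(values), n))
  }
  # full knot vector with boundary duplication: n + k knots
  t <- c(rep(knots[1], k), knots[2:(n - 1)], rep(knots[n], k))
  if (n == 2) t <- c(rep(knots[1], k), rep(knots[2], k))
  x <- pmin(pmax(values, knots[1]), knots[n])
  mspline <- function(i, ord, xx) {
    if (ord == 1) {
      d <- t[i + 1] - t[i]
      return(ifelse(xx >= t[i] & (xx < t[i + 1] | (t[i + 1] == t[n + k] & xx <= t[i + 1])),
                    ifelse(d > 0, 1 / d, 0), 0))
    }
    d <- t[i + ord] - t[i]
    if (d <= 0) return(rep(0, length(xx)))
    ord * ((xx - t[i]) * mspline(i, ord - 1, xx) +
             (t[i + ord] - xx) * mspline(i + 1, ord - 1, xx)) /
      ((ord - 1) * d)
  }
  # I-spline via cumulative trapezoid integration of each M-spline on a
  # fine grid, then interpolation; exact enough (grid of 2048) and general
  grid <- seq(knots[1], knots[n], length.out = 2048)
  out <- matrix(0, length(x), n)
  for (i in seq_len(n)) {
    mg <- mspline(i, k, grid)
    Ig <- c(0, cumsum((mg[-1] + mg[-length(mg)]) / 2 * diff(grid)))
    Ig <- Ig / max(Ig[length(Ig)], 1e-300)   # normalize to reach exactly 1
    out[, i] <- stats::approx(grid, Ig, xout = x, rule = 2)$y
  }
  out
}

#' Generalized dissimilarity model
#'
#' Fits d_ij = 1 - exp(-eta_ij) with
#' eta_ij = beta0 + sum_k sum_s beta_ks |I_ks(x_ik) - I_ks(x_jk)| (+
#' optional geographic-distance splines evaluated at the pair distance),
#' all coefficients constrained non-negative. Fitting is iteratively
#' reweighted non-negative least squares on the complementary-log
#' working response with binomial-type weights, to convergence
#' (|delta deviance| < 1e-8) or 100 iterations.
#'
#' @param gen_dissim pairwise biological dissimilarity (matrix or
#'   \code{dist_matrix}) in [0, 1); rescale first if needed.
#' @param env sites x variables table (rownames or \code{pop} column
#'   matching the dissimilarity labels).
#' @param coords optional data.frame with \code{lat}, \code{lon}; when
#'   given, great-circle distance enters as an additional spline predictor.
#' @param n_splines I-splines per predictor (default 3, knots at
#'   min/median/max).
#' @return An object of class \code{gdm_model}: \code{intercept},
#'   \code{coefficients} (named non-negative vector, n_splines per
#'   predictor), \code{knots} (per predictor), \code{deviance},
#'   \code{null_deviance}, \code{deviance_explained}, \code{converged},
#'   \code{predictors}, \code{use_geo}. Methods: \code{print},
#'   \code{coef}, \code{predict} (see \code{\link{predict.gdm_model}}).
#' @export
gdm_fit <- function(gen_dissim, env, coords = NULL, n_splines = 3) {
  D <- unclass_dist(gen_dissim)
  if (any(D < 0)) stop("negative dissimilarities")
  if (any(D[upper.tri(D)] >= 1)) stop("dissimilarities must be below 1; rescale first")
  n <- nrow(D)
  if (n < 6) stop("need at least 6 sites")
  env <- as.data.frame(env)
  if (!is.null(env$pop)) {
    rownames(env) <- env$pop
    env$pop <- NULL
  }
  if (!is.null(rownames(D)) && all(rownames(D) %in% rownames(env))) {
    env <- env[rownames(D), , drop = FALSE]
  }
  stopifnot(nrow(env) == n)
  vars <- names(env)[vapply(env, is.numeric, logical(1))]
  ut <- which(upper.tri(D), arr.ind = TRUE)
  y <- D[upper.tri(D)]

  knots <- list(); Xcols <- list()
  for (v in vars) {
    bas <- ispline_basis(env[[v]], n_splines)
    knots[[v]] <- bas$knots
    Ix <- bas$basis
    Xcols[[v]] <- abs(Ix[ut[, 1], , drop = FALSE] -
                        Ix[ut[, 2], , drop = FALSE])
    colnames(Xcols[[v]]) <- paste0(v, "_s", seq_len(n_splines))
  }
  use_geo <- !is.null(coords)
  if (use_geo) {
    gd <- unclass_dist(build_distances(coords)$geo)
    dvec <- gd[upper.tri(gd)]
    gknots <- c(0, unname(stats::quantile(dvec,
      seq(0, 1, length.out = n_splines)[-1])))
    knots[["geo"]] <- gknots
    Xcols[["geo"]] <- ispline_eval(dvec, gknots)
    colnames(Xcols[["geo"]]) <- paste0("geo_s", seq_len(n_splines))
  }
  X <- cbind(intercept = 1, do.call(cbind, Xcols))

  dev_of <- function(mu) {
    mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    yy <- pmin(pmax(y, 1e-9), 1 - 1e-9)
    sum(2 * (yy * log(yy / mu) + (1 - yy) * log((1 - yy) / (1 - mu))))
  }
  irls <- function(Xm) {
    beta <- rep(0, ncol(Xm))
    beta[1] <- -log(1 - pmin(max(mean(y), 1e-6), 1 - 1e-6))
    dev_old <- Inf; converged <- FALSE
    for (it in seq_len(100)) {
      eta <- drop(Xm %*% beta)
      mu <- 1 - exp(-eta)
      mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
      dmu <- 1 - mu                         # d mu / d eta = exp(-eta)
      z <- eta + (y - mu) / dmu
      w <- dmu^2 / (mu * (1 - mu))          # binomial-type variance
      sw <- sqrt(w)
      fit <- pracma::lsqnonneg(Xm * sw, z * sw)
      beta <- fit$x
      dev <- dev_of(1 - exp(-drop(Xm %*% beta)))
      if (abs(dev_old - dev) < 1e-8) { converged <- TRUE; break }
      dev_old <- dev
    }
    list(beta = beta, deviance = dev, converged = converged)
  }
  full <- irls(X)
  if (!full$converged && !is.finite(full$deviance)) {
    stop("GDM fit failed to converge; deviance trace not finite")
  }
  null <- irls(X[, 1, drop = FALSE])
  beta <- full$beta
  names(beta) <- colnames(X)
  structure(list(intercept = beta[[1]], coefficients = beta[-1],
                 knots = knots, n_splines = n_splines,
                 deviance = full$deviance,
                 null_deviance = null$deviance,
                 deviance_explained =
                   1 - full$deviance / null$deviance,
                 converged = full$converged,
                 predictors = vars, use_geo = use_geo),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("GDM: %d predictors%s, %d I-splines each\n",
              length(x$predictors),
              if (x$use_geo) " + geographic distance" else "",
              x$n_splines))
  cat(sprintf("  intercept %.4g; deviance explained %.1f%%%s\n",
              x$intercept, 100 * x$deviance_explained,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.gdm_model <- function(object, ...) {
  c(intercept = object$intercept, object$coefficients)
}

#' Predict compositional dissimilarity from a GDM
#'
#' @param object a \code{gdm_model}.
#' @param env_a,env_b data.frames of raw environmental values (columns =
#'   the model's predictors), one row per pair.
#' @param geo_dist great-circle distances (km) per pair, if the model was
#'   fitted with geographic splines (default 0).
#' @param include_intercept include beta0 in the linear predictor (default
#'   TRUE for dissimilarity prediction; offsets use FALSE so that identical
#'   environments map to exactly zero).
#' @param ... unused.
#' @return predicted dissimilarities in [0, 1).
#' @export
predict.gdm_model <- function(object, env_a, env_b, geo_dist = 0,
                              include_intercept = TRUE, ...) {
  env_a <- as.data.frame(env_a); env_b <- as.data.frame(env_b)
  eta <- if (include_intercept) rep(object$intercept, nrow(env_a)) else
    rep(0, nrow(env_a))
  for (v in object$predictors) {
    Ia <- ispline_eval(env_a[[v]], object$knots[[v]])
    Ib <- ispline_eval(env_b[[v]], object$knots[[v]])
    b <- object$coefficients[paste0(v, "_s", seq_len(object$n_splines))]
    eta <- eta + drop(abs(Ia - Ib) %*% b)
  }
  if (object$use_geo) {
    Ig <- ispline_eval(rep_len(geo_dist, nrow(env_a)),
                       object$knots[["geo"]])
    b <- object$coefficients[paste0("geo_s", seq_len(object$n_splines))]
    eta <- eta + drop(Ig %*% b)
  }
  1 - exp(-eta)
}

#' GDM local, forward and reverse genetic offsets
#'
#' Local offset: predicted dissimilarity between a cell's current and
#' future environment. Forward offset: the minimum predicted dissimilarity
#' between the cell's current environment and the future environment of any
#' unmasked cell (no dispersal limitation); the chosen target's great-circle
#' distance (km) and initial bearing (degrees clockwise from north) are
#' recorded. Reverse offset: the minimum dissimilarity between the cell's
#' future environment and any cell's current environment. All offsets use
#' the spline terms only (no intercept), so a null scenario gives exact
#' zeros. Argmin ties break by smallest great-circle distance, then lowest
#' cell index.
#'
#' @param model a \code{gdm_model}.
#' @param current,future \code{\link{climate_grid}}s sharing mask and
#'   variables.
#' @return An object of class \code{offset_surface}: data.frame with cell,
#'   lat, lon, local, forward, reverse, fwd_cell, distance_km, bearing_deg.
#' @export
gdm_offsets <- function(model, current, future) {
  stopifnot(inherits(current, "climate_grid"),
            inherits(future, "climate_grid"),
            identical(current$mask, future$mask))
  if (sum(current$mask) == 0) stop("empty mask: no unmasked cells")
  cur <- grid_cells(current); fut <- grid_cells(future)
  C <- nrow(cur)
  # transformed coordinates: I-spline values scaled by sqrt of nothing --
  # pairwise eta is a weighted L1 distance in this space
  tr <- function(cells_df) {
    do.call(cbind, lapply(model$predictors, function(v) {
      Ixy <- ispline_eval(cells_df[[v]], model$knots[[v]])
      b <- model$coefficients[paste0(v, "_s",
                                     seq_len(model$n_splines))]
      Ixy * rep(b, each = nrow(Ixy))
    }))
  }
  Tc <- tr(cur); Tf <- tr(fut)
  local <- 1 - exp(-rowSums(abs(Tc - Tf)))
  forward <- numeric(C); fwd_cell <- integer(C)
  reverse <- numeric(C)
  pts <- cbind(cur$lon, cur$lat)
  for (i in seq_len(C)) {
    eta_f <- colSums(abs(t(Tf) - Tc[i, ]))
    off_f <- 1 - exp(-eta_f)
    m <- min(off_f)
    cand <- which(off_f <= m + 1e-15)
    if (length(cand) > 1) {
      dd <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                     pts[cand, , drop = FALSE], r = 6371000)
      cand <- cand[order(dd, cur$cell[cand])]
    }
    forward[i] <- m
    fwd_cell[i] <- cand[1]
    eta_r <- colSums(abs(t(Tc) - Tf[i, ]))
    reverse[i] <- min(1 - exp(-eta_r))
  }
  dist_km <- ifelse(fwd_cell == seq_len(C), 0,
                    geosphere::distHaversine(pts, pts[fwd_cell, ,
                                                      drop = FALSE],
                                             r = 6371000) / 1000)
  bearing <- ifelse(fwd_cell == seq_len(C), NA_real_,
                    (geosphere::bearing(pts, pts[fwd_cell, , drop = FALSE]) +
                       360) %% 360)
  out <- data.frame(cell = cur$cell, lat = cur$lat, lon = cur$lon,
                    local = local, forward = forward, reverse = reverse,
                    fwd_cell = cur$cell[fwd_cell],
                    distance_km = dist_km, bearing_deg = bearing)
  class(out) <- c("offset_surface", "data.frame")
  attr(out, "scenario") <- future$scenario
  out
}

#' Min-max RGB composite of the three offset metrics
#'
#' @param surface an \code{offset_surface}.
#' @return data.frame cell, lat, lon, r (local), g (forward), b (reverse),
#'   each min-max scaled to [0, 1].
#' @export
offsets_rgb <- function(surface) {
  sc <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  data.frame(cell = surface$cell, lat = surface$lat, lon = surface$lon,
             r = sc(surface$local), g = sc(surface$forward),
             b = sc(surface$reverse))
}
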