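#' Simulation configuration
#'
#' Defines a synthetic landscape-genomics study: a gridded landscape with
#' spatially autocorrelated environmental layers, populations placed on the
#' grid, neutral loci drifting under a Balding-Nichols model, adaptive loci
#' carrying logistic allele-frequency clines on an environmental variable,
#' and a future scenario obtained by per-variable additive shifts.
#'
#' Defaults emulate a range-wide RAD-seq study of a montane tree: about two
#' dozen populations of eight trees on a climate gradient, two thousand SNPs
#' with roughly one adaptive locus in forty, multilocus differentiation near
#' F_ST = 0.1, and 11\% missing genotypes.
#'
#' @param grid_rows,grid_cols landscape size in cells.
#' @param n_env number of environmental layers.
#' @param autocorr_range spatial correlation length, in cells (> 0).
#' @param n_pops,n_ind_per_pop populations and diploid individuals per
#'   population.
#' @param n_neutral,n_adaptive locus counts (\code{n_adaptive} may be 0).
#' @param fst_target Balding-Nichols drift parameter F in (0, 1); the
#'   expected multilocus F_ST of the neutral loci.
#' @param beta per-adaptive-locus cline slope on the logit scale (recycled).
#' @param adaptive_var index of the environmental variable driving each
#'   adaptive locus (recycled; default: variable 1).
#' @param missing_rate fraction of genotypes masked missing, completely at
#'   random, in [0, 1).
#' @param future_delta per-variable additive shift defining the future
#'   scenario (recycled to \code{n_env}); layers are standardized, so a
#'   delta of 1 is one landscape standard deviation.
#' @param seed RNG seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(grid_rows = 40, grid_cols = 40, n_env = 3,
                       autocorr_range = 8, n_pops = 26, n_ind_per_pop = 8,
                       n_neutral = 1950, n_adaptive = 50, fst_target = 0.1,
                       beta = 1.5, adaptive_var = 1, missing_rate = 0.11,
                       future_delta = 1, seed = 1) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              n_env = as.integer(n_env),
              autocorr_range = autocorr_range,
              n_pops = as.integer(n_pops),
              n_ind_per_pop = as.integer(n_ind_per_pop),
              n_neutral = as.integer(n_neutral),
              n_adaptive = as.integer(n_adaptive),
              fst_target = fst_target,
              beta = rep_len(beta, max(1L, as.integer(n_adaptive))),
              adaptive_var = rep_len(as.integer(adaptive_var),
                                     max(1L, as.integer(n_adaptive))),
              missing_rate = missing_rate,
              future_delta = rep_len(future_delta, as.integer(n_env)),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(grid_rows >= 1, grid_cols >= 1, n_env >= 1, n_pops >= 1,
              n_ind_per_pop >= 1, n_neutral >= 1, n_adaptive >= 0)
    if (autocorr_range <= 0) stop("autocorr_range must be positive")
    if (fst_target <= 0 || fst_target >= 1) stop("fst_target must be in (0,1)")
    if (missing_rate < 0 || missing_rate >= 1) {
      stop("missing_rate must be in [0,1)")
    }
    if (any(adaptive_var > n_env)) stop("adaptive_var exceeds n_env")
  })
  structure(cfg, class = "sim_config")
}

# Gaussian random field on a grid by circular (FFT) convolution of white
# noise with a Gaussian kernel of bandwidth `range` cells; wrap-around
# artifacts are negligible at the landscape scales used here.
gaussian_field <- function(nr, nc, range) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * range^2))
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  f
}

#' Simulate current and future climate landscapes
#'
#' Each environmental layer is a Gaussian random field with the requested
#' correlation length, standardized to mean 0 and sd 1 over unmasked cells.
#' The future scenario adds \code{future_delta} per variable and shares the
#' mask.
#'
#' @param config a \code{\link{sim_config}}.
#' @param mask optional logical matrix of suitable cells (default all
#'   suitable).
#' @return list with elements \code{current} and \code{future}, both
#'   \code{\link{climate_grid}} objects.
#' @export
simulate_landscape <- function(config, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  # square cells (~10 km) anchored at a subtropical-island window
  cs <- 0.09
  lon <- 120.0 + cs * (seq_len(nc) - 1)
  lat <- 25.3 - cs * (seq_len(nr) - 1)
  cur <- list()
  for (v in seq_len(config$n_env)) {
    f <- gaussian_field(nr, nc, config$autocorr_range)
    mu <- mean(f[mask]); sd <- stats::sd(f[mask])
    cur[[paste0("env", v)]] <- (f - mu) / sd
  }
  fut <- mapply(function(l, d) l + d, cur, config$future_delta,
                SIMPLIFY = FALSE)
  list(current = climate_grid(cur, lat, lon, mask, "current"),
       future = climate_grid(fut, lat, lon, mask, "future"))
}

# deterministic near-regular placement of n sites on the unmasked cells:
# regular lattice spacing, seeded jitter, snap to nearest unmasked cell
place_populations <- function(config, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (config$n_pops > sum(mask)) {
    stop("n_pops exceeds the number of unmasked cells")
  }
  k <- ceiling(sqrt(config$n_pops))
  rows <- seq(1, nr, length.out = k + 2)[2:(k + 1)]
  cols <- seq(1, nc, length.out = k + 2)[2:(k + 1)]
  pts <- expand.grid(r = rows, c = cols)[seq_len(config$n_pops), ]
  jit <- (nr / (k + 2)) / 4
  pts$r <- pts$r + stats::runif(config$n_pops, -jit, jit)
  pts$c <- pts$c + stats::runif(config$n_pops, -jit, jit)
  ok <- which(mask)
  okrc <- arrayInd(ok, dim(mask))
  cells <- integer(config$n_pops)
  for (i in seq_len(config$n_pops)) {
    d2 <- (okrc[, 1] - pts$r[i])^2 + (okrc[, 2] - pts$c[i])^2
    # avoid stacking two populations on one cell when possible
    d2[ok %in% cells[seq_len(i - 1)]] <- d2[ok %in% cells[seq_len(i - 1)]] + nr * nc
    cells[i] <- ok[which.min(d2)]
  }
  cells
}

#' Simulate genotypes on a landscape with recorded ground truth
#'
#' Neutral loci: ancestral frequency p0 ~ Uniform(0.05, 0.95); population
#' frequencies drawn from the Balding-Nichols Beta distribution with drift
#' parameter F = \code{fst_target}. Adaptive loci additionally shift the
#' drawn frequency on the logit scale by beta times the driving variable's
#' standardized value at the population's cell. Genotypes are Binomial(2,
#' freq); genotypes are masked missing completely at random. Frequencies are
#' clipped to [0.001, 0.999] before sampling; loci that happen to be
#' monomorphic in the realized sample are retained.
#'
#' @param config a \code{\link{sim_config}}.
#' @param climate the \emph{current} \code{\link{climate_grid}} (from
#'   \code{\link{simulate_landscape}}).
#' @param future optional future \code{climate_grid}; when supplied, the
#'   ground truth includes each cell's true mean absolute allele-frequency
#'   change under the scenario.
#' @return list with \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{env} (populations x variables data.frame of the environment at
#'   each population's cell), and \code{truth} (adaptive locus ids, p0,
#'   beta, driving variable per locus, population cells, per-population true
#'   allele frequencies, and \code{cell_offset}: per-cell true mean |delta
#'   freq| over adaptive loci, when \code{future} is given).
#' @export
simulate_genotypes <- function(config, climate, future = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(climate, "climate_grid"))
  set.seed(config$seed + 1L)
  mask <- climate$mask
  cells <- place_populations(config, mask)
  rc <- arrayInd(cells, dim(mask))
  n_pops <- config$n_pops
  n_loci <- config$n_neutral + config$n_adaptive
  n_ind <- n_pops * config$n_ind_per_pop
  fst <- config$fst_target

  env <- sapply(climate$layers, function(l) l[cells])
  env <- matrix(env, nrow = n_pops,
                dimnames = list(NULL, names(climate$layers)))

  p0 <- stats::runif(n_loci, 0.05, 0.95)
  adaptive_ids <- if (config$n_adaptive > 0) {
    config$n_neutral + seq_len(config$n_adaptive)
  } else integer(0)
  beta <- rep(0, n_loci)
  driver <- rep(NA_integer_, n_loci)
  if (config$n_adaptive > 0) {
    beta[adaptive_ids] <- config$beta
    driver[adaptive_ids] <- config$adaptive_var
  }

  # Balding-Nichols population frequencies
  shape_mult <- (1 - fst) / fst
  freq <- matrix(0, n_pops, n_loci)
  for (l in seq_len(n_loci)) {
    freq[, l] <- stats::rbeta(n_pops, p0[l] * shape_mult,
                              (1 - p0[l]) * shape_mult)
  }
  # logistic clines for adaptive loci
  for (l in adaptive_ids) {
    z <- env[, driver[l]]
    freq[, l] <- stats::plogis(stats::qlogis(pmin(pmax(freq[, l], 1e-6),
                                                  1 - 1e-6)) + beta[l] * z)
  }
  freq <- pmin(pmax(freq, 0.001), 0.999)

  pop_labels <- sprintf("P%02d", seq_len(n_pops))
  pop_of_ind <- rep(seq_len(n_pops), each = config$n_ind_per_pop)
  geno <- matrix(stats::rbinom(n_ind * n_loci, 2,
                               freq[pop_of_ind, ]), n_ind, n_loci)
  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA
  }

  individuals <- data.frame(
    id = sprintf("%s_i%02d", pop_labels[pop_of_ind],
                 sequence(rep(config$n_ind_per_pop, n_pops))),
    pop = pop_labels[pop_of_ind],
    lat = climate$lat[rc[, 1]][pop_of_ind],
    lon = climate$lon[rc[, 2]][pop_of_ind])
  g <- genotype_matrix(geno, individuals = individuals)

  truth <- list(adaptive_ids = adaptive_ids, p0 = p0, beta = beta,
                driver = driver, cells = cells, pop_freq = freq,
                pop_labels = pop_labels)
  if (!is.null(future) && config$n_adaptive > 0) {
    idx <- which(mask)
    delta <- matrix(0, length(idx), config$n_adaptive)
    for (k in seq_len(config$n_adaptive)) {
      l <- adaptive_ids[k]
      zc <- climate$layers[[driver[l]]][idx]
      zf <- future$layers[[driver[l]]][idx]
      base <- stats::qlogis(p0[l])
      delta[, k] <- abs(stats::plogis(base + beta[l] * zf) -
                          stats::plogis(base + beta[l] * zc))
    }
    truth$cell_offset <- data.frame(cell = idx, offset = rowMeans(delta))
  }
  env_df <- data.frame(pop = pop_labels, env, check.names = FALSE)
  list(genotypes = g, env = env_df, truth = truth)
}
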