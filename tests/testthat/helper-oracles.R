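# Independent oracle implementations used to cross-check the package; all
# deliberately brute-force and kept separate from the code paths they test.

# Weir & Cockerham (1984) theta components for one locus, scalar arithmetic
# straight from the published formulas.
wc_oracle_locus <- function(geno_by_pop) {
  n <- vapply(geno_by_pop, function(g) sum(!is.na(g)), numeric(1))
  keep <- n > 0
  geno_by_pop <- geno_by_pop[keep]; n <- n[keep]
  r <- length(n)
  p <- vapply(geno_by_pop, function(g) sum(g, na.rm = TRUE), numeric(1)) / (2 * n)
  h <- vapply(geno_by_pop, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# step-up BH from the definition, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# folded SFS by exhaustive enumeration of all chromosome subsets
sfs_enum_oracle <- function(allele_counts, sample_sizes, m) {
  half <- floor(m / 2)
  spec <- numeric(m + 1)
  for (l in seq_along(allele_counts)) {
    n <- sample_sizes[l]; d <- allele_counts[l]
    chroms <- c(rep(1, d), rep(0, n - d))
    subs <- utils::combn(n, m)
    counts <- apply(subs, 2, function(ix) sum(chroms[ix]))
    for (k in 0:m) spec[k + 1] <- spec[k + 1] + mean(counts == k)
  }
  folded <- numeric(half)
  for (k in seq_len(half)) {
    folded[k] <- spec[k + 1] + if (m - k != k) spec[m - k + 1] else 0
  }
  list(sfs = folded, monomorphic = spec[1] + spec[m + 1])
}

# Moran's I with rook adjacency on a full grid
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; wsum <- 0
  num <- sum(z[-nr, ] * z[-1, ]) * 2 + sum(z[, -nc] * z[, -1]) * 2
  wsum <- 2 * ((nr - 1) * nc + nr * (nc - 1))
  (length(m) / wsum) * (num / sum(z^2))
}

# additive distance matrix from a 4-taxon tree ((A:a,B:b):m,(C:c,D:d));
tree4_matrix <- function(a, b, c, d, m) {
  M <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  M["A", "B"] <- a + b
  M["A", "C"] <- a + m + c
  M["A", "D"] <- a + m + d
  M["B", "C"] <- b + m + c
  M["B", "D"] <- b + m + d
  M["C", "D"] <- c + d
  M + t(M)
}

# small simulated study shared by several tests
quick_sim <- function(seed = 1, n_pops = 12, n_ind = 6, n_neutral = 150,
                      n_adaptive = 10, beta = 1.5, fst = 0.1,
                      future_delta = 1, n_env = 3, missing = 0.11) {
  cfg <- sim_config(grid_rows = 25, grid_cols = 25, n_env = n_env,
                    autocorr_range = 5, n_pops = n_pops,
                    n_ind_per_pop = n_ind, n_neutral = n_neutral,
                    n_adaptive = n_adaptive, fst_target = fst,
                    beta = beta, missing_rate = missing,
                    future_delta = future_delta, seed = seed)
  land <- simulate_landscape(cfg)
  sim <- simulate_genotypes(cfg, land$current, land$future)
  list(cfg = cfg, land = land, sim = sim)
}
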