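make_grids <- function(vals_cur, vals_fut, nr = 3, nc = 3) {
  lat <- seq(25, 24, length.out = nr)
  lon <- seq(120, 121, length.out = nc)
  cg <- climate_grid(lapply(vals_cur, function(v) matrix(v, nr, nc)),
                     lat, lon, scenario = "current")
  fg <- climate_grid(lapply(vals_fut, function(v) matrix(v, nr, nc)),
                     lat, lon, scenario = "future")
  list(cur = cg, fut = fg)
}

test_that("RONA obeys its closed form and the null scenario", {
  q <- quick_sim(seed = 81, n_pops = 15, n_ind = 8, n_neutral = 20,
                 n_adaptive = 10, beta = 2, missing = 0)
  g <- q$sim$genotypes
  env <- q$sim$env
  # null: future = current -> all zero
  sig <- list(env1 = colnames(g$geno)[q$sim$truth$adaptive_ids])
  r0 <- rona(g, env, env, sig)
  expect_true(all(r0$rona == 0))
  # single locus closed form |slope * delta|
  g1 <- subset_genotypes(g, loci = q$sim$truth$adaptive_ids[1])
  pf <- allele_freqs(g1, by_pop = TRUE)
  fit <- lm(pf[, 1] ~ env$env1)
  fut <- env; fut$env1 <- fut$env1 + c(0.5, rep(1, 14))
  r1 <- rona(g1, env, fut, list(env1 = colnames(g1$geno)))
  expect_equal(unname(r1$rona[, "env1"]),
               abs(coef(fit)[2]) * abs(fut$env1 - env$env1),
               tolerance = 1e-12)
  # variable ranking counts significant loci, top three flagged
  sig3 <- list(env1 = colnames(g$geno)[1:5], env2 = colnames(g$geno)[1:3],
               env3 = colnames(g$geno)[1])
  r3 <- rona(g, env, fut, sig3)
  expect_equal(r3$ranking$variable, c("env1", "env2", "env3"))
  expect_true(all(r3$ranking$top3))
  expect_warning(rona(g, env, fut, list(env1 = colnames(g$geno)[1],
                                        env2 = character(0))),
                 "env2")
})

test_that("weighted RONA tracks the ground-truth allele-frequency change", {
  errs <- vapply(1:5, function(s) {
    q <- quick_sim(seed = 820 + s, n_pops = 20, n_ind = 8,
                   n_neutral = 50, n_adaptive = 25, beta = 1.5,
                   future_delta = c(1, 0, 0), missing = 0)
    g <- q$sim$genotypes
    tr <- q$sim$truth
    sig <- list(env1 = colnames(g$geno)[tr$adaptive_ids])
    fut <- q$sim$env
    fut$env1 <- fut$env1 + 1
    rr <- rona(g, q$sim$env, fut, sig)
    # ground truth: mean |delta p| per population over adaptive loci
    truth_pop <- vapply(seq_len(20), function(j) {
      mean(vapply(tr$adaptive_ids, function(l) {
        eta <- qlogis(tr$p0[l])
        z <- q$sim$env$env1[j]
        abs(plogis(eta + tr$beta[l] * (z + 1)) -
              plogis(eta + tr$beta[l] * z))
      }, numeric(1)))
    }, numeric(1))
    abs(mean(rr$rona[, "env1"]) - mean(truth_pop)) / mean(truth_pop)
  }, numeric(1))
  expect_lte(mean(errs), 0.20)
})

test_that("gradient forest concentrates importance on the driving variable", {
  set.seed(83)
  q <- quick_sim(seed = 83, n_pops = 20, n_ind = 8, n_neutral = 5,
                 n_adaptive = 15, beta = 2, n_env = 1, missing = 0)
  g <- subset_genotypes(q$sim$genotypes, loci = q$sim$truth$adaptive_ids)
  env <- q$sim$env
  env$noise1 <- rnorm(20); env$noise2 <- rnorm(20)
  gf <- gf_fit(g, env, n_trees = 80, seed = 1)
  expect_gte(gf$importance[["env1"]] / sum(gf$importance), 0.80)
  # turnover functions are monotone and bounded by the variable's importance
  for (v in gf$variables) {
    tv <- gf$turnover[[v]]
    if (length(tv$cum) == 0) next
    expect_true(all(diff(tv$cum) >= -1e-12))
    expect_equal(max(tv$cum), gf$importance[[v]], tolerance = 1e-10)
  }
  # permuting environment rows destroys the signal
  set.seed(9)
  envp <- env[sample(nrow(env)), ]
  envp$pop <- env$pop
  gfp <- tryCatch(gf_fit(g, envp, n_trees = 80, seed = 1),
                  error = function(e) NULL)
  r2_perm <- if (is.null(gfp)) 0 else sum(gfp$locus_r2)
  expect_gte(sum(gf$locus_r2), 5 * max(r2_perm, 1e-9))
})

test_that("gradient-forest offsets are zero under the null and match hand arithmetic", {
  q <- quick_sim(seed = 85, n_pops = 12, n_ind = 6, n_neutral = 5,
                 n_adaptive = 10, beta = 1.5, future_delta = 0)
  g <- subset_genotypes(q$sim$genotypes, loci = q$sim$truth$adaptive_ids)
  gf <- gf_fit(g, q$sim$env, n_trees = 50, seed = 1)
  off0 <- gf_offset(gf, q$land$current, q$land$future)
  expect_true(all(off0$offset == 0))
  # hand-specified step turnover on a 3x3 grid
  model <- structure(list(
    turnover = list(e1 = list(pos = c(0, 1), cum = c(0.3, 0.5)),
                    e2 = list(pos = 0.5, cum = 0.2)),
    importance = c(e1 = 0.5, e2 = 0.2),
    locus_r2 = c(l1 = 0.5), n_trees = 1, max_depth = 1,
    corr_threshold = 0.5, variables = c("e1", "e2")),
    class = "gf_model")
  grids <- make_grids(list(e1 = -1, e2 = 0), list(e1 = 2, e2 = 1))
  off <- gf_offset(model, grids$cur, grids$fut)
  # e1: F(-1)=0 -> F(2)=0.5 ; e2: F(0)=0 -> F(1)=0.2
  expect_equal(off$offset, rep(sqrt(0.5^2 + 0.2^2), 9), tolerance = 1e-12)
  # monotonicity: larger shift of the dominant variable never lowers offset
  grids2 <- make_grids(list(e1 = -1, e2 = 0), list(e1 = 0.5, e2 = 1))
  off2 <- gf_offset(model, grids2$cur, grids2$fut)
  expect_true(all(off$offset >= off2$offset - 1e-12))
  expect_error(gf_offset(model, q$land$current, q$land$future), "missing")
})

test_that("gradient-forest RGB map stays in [0,1] and matches the PCA oracle", {
  q <- quick_sim(seed = 87, n_pops = 15, n_ind = 6, n_neutral = 5,
                 n_adaptive = 12, beta = 1.5)
  g <- subset_genotypes(q$sim$genotypes, loci = q$sim$truth$adaptive_ids)
  gf <- gf_fit(g, q$sim$env, n_trees = 50, seed = 1)
  rgb <- gf_rgb_map(gf, q$land$current)
  expect_true(all(rgb$r >= 0 & rgb$r <= 1))
  expect_true(all(rgb$g >= 0 & rgb$g <= 1))
  expect_true(all(rgb$b >= 0 & rgb$b <= 1))
  sc <- attr(rgb, "scores")
  Tm <- gf_transform(gf, grid_cells(q$land$current)[gf$variables])
  pr <- prcomp(Tm, center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    expect_equal(abs(cor(sc[, k], pr$x[, k])), 1, tolerance = 1e-8)
  }
  # constant grid -> a single color
  cg <- make_grids(list(env1 = 1, env2 = 2, env3 = 0),
                   list(env1 = 1, env2 = 2, env3 = 0))
  rgbc <- suppressWarnings(gf_rgb_map(gf, cg$cur))
  expect_equal(length(unique(paste(rgbc$r, rgbc$g, rgbc$b))), 1)
})

test_that("I-splines are monotone and GDM honors its degenerate cases", {
  x <- seq(0, 10, length.out = 50)
  bas <- ispline_basis(x, 3)
  for (j in 1:3) {
    expect_true(all(diff(bas$basis[, j]) >= -1e-10))
    expect_equal(bas$basis[1, j], 0, tolerance = 1e-10)
    expect_equal(bas$basis[50, j], 1, tolerance = 1e-3)
  }
  # identical environments: spline coefficients 0, constant prediction
  set.seed(93)
  n <- 8
  D <- matrix(0.3, n, n); diag(D) <- 0
  env_const <- data.frame(e = rep(1, n))
  gdm0 <- gdm_fit(dist_matrix(D, labels = paste0("P", 1:n)), env_const)
  expect_true(all(gdm0$coefficients < 1e-8))
  expect_equal(unique(round(predict(gdm0,
                                    data.frame(e = 1:3),
                                    data.frame(e = 4:6)), 10)),
               round(1 - exp(-gdm0$intercept), 10))
  Dneg <- D; Dneg[1, 2] <- Dneg[2, 1] <- -0.1
  expect_error(gdm_fit(Dneg, env_const), "negative")
  expect_error(gdm_fit(D[1:4, 1:4], env_const[1:4, , drop = FALSE]),
               "6 sites")
  Dbig <- D; Dbig[1, 2] <- Dbig[2, 1] <- 1.2
  expect_error(gdm_fit(Dbig, env_const), "below 1")
})

test_that("GDM recovers a known single-predictor generator", {
  set.seed(97)
  n <- 14
  env <- data.frame(e = sort(runif(n, 0, 4)))
  labs <- paste0("P", 1:n)
  bas <- ispline_basis(env$e, 3)
  beta_true <- c(0.4, 0.8, 0.3)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    eta <- sum(beta_true * abs(bas$basis[i, ] - bas$basis[j, ]))
    D[i, j] <- D[j, i] <- 1 - exp(-eta)
  }
  fit <- gdm_fit(dist_matrix(D, labels = labs), env)
  expect_gte(fit$deviance_explained, 0.95)
  pred <- predict(fit,
                  env[rep(1:n, each = n), , drop = FALSE],
                  env[rep(1:n, times = n), , drop = FALSE])
  rmse <- sqrt(mean((pred - as.vector(t(D)))^2))
  expect_lte(rmse, 0.02)
  # monotone in the predictor difference
  pa <- predict(fit, data.frame(e = rep(1, 20)),
                data.frame(e = seq(1, 4, length.out = 20)))
  expect_true(all(diff(pa) >= -1e-9))
})

test_that("GDM offsets satisfy the null, the bounds and the brute-force oracle", {
  set.seed(101)
  n <- 14
  env <- data.frame(e1 = sort(runif(n, -2, 2)), e2 = rnorm(n))
  labs <- paste0("P", 1:n)
  D <- as.matrix(dist(env$e1)) * 0.1 +
    matrix(runif(n * n, 0, 0.01), n)
  D <- (D + t(D)) / 2; diag(D) <- 0
  gdm <- gdm_fit(dist_matrix(D, labels = labs), env)
  grids <- make_grids(list(e1 = c(-1, 0, 1, -0.5, 0.5, 1.5, -1.5, 0.2, 0.8),
                           e2 = runif(9)),
                      list(e1 = c(0, 1, 2, 0.5, 1.5, 2.5, -0.5, 1.2, 1.8),
                           e2 = runif(9)))
  # null scenario: everything exactly zero, distance 0
  off0 <- gdm_offsets(gdm, grids$cur, grids$cur)
  expect_true(all(off0$local == 0))
  expect_true(all(off0$forward == 0))
  expect_true(all(off0$reverse == 0))
  expect_true(all(off0$distance_km == 0))
  # bounds and exhaustive double-loop oracle on the 3x3 grid
  off <- gdm_offsets(gdm, grids$cur, grids$fut)
  expect_true(all(off$forward <= off$local + 1e-12))
  expect_true(all(off$reverse <= off$local + 1e-12))
  cells_c <- grid_cells(grids$cur); cells_f <- grid_cells(grids$fut)
  pred_pair <- function(i, j) {
    predict(gdm, cells_c[i, c("e1", "e2")], cells_f[j, c("e1", "e2")],
            include_intercept = FALSE)
  }
  for (i in 1:9) {
    fwd_oracle <- min(vapply(1:9, function(j) pred_pair(i, j), numeric(1)))
    expect_equal(off$forward[i], fwd_oracle, tolerance = 1e-10)
    rev_oracle <- min(vapply(1:9, function(j) {
      predict(gdm, cells_c[j, c("e1", "e2")], cells_f[i, c("e1", "e2")],
              include_intercept = FALSE)
    }, numeric(1)))
    expect_equal(off$reverse[i], rev_oracle, tolerance = 1e-10)
    expect_equal(off$local[i], pred_pair(i, i), tolerance = 1e-10)
  }
  # bearing of a due-north target
  b <- geosphere::bearing(c(121, 24), c(121, 25))
  expect_lt(abs(b %% 360), 0.5)
  expect_error(gdm_offsets(gdm, climate_grid(list(e1 = matrix(1, 2, 2),
                                                  e2 = matrix(1, 2, 2)),
                                             c(25, 24), c(120, 121),
                                             mask = matrix(FALSE, 2, 2)),
                           climate_grid(list(e1 = matrix(1, 2, 2),
                                             e2 = matrix(1, 2, 2)),
                                        c(25, 24), c(120, 121),
                                        mask = matrix(FALSE, 2, 2))),
               "empty mask")
})

test_that("offsets grow with the magnitude of the climate shift", {
  q <- quick_sim(seed = 103, n_pops = 15, n_ind = 6, n_neutral = 30,
                 n_adaptive = 15, beta = 1.5, future_delta = 0)
  g <- subset_genotypes(q$sim$genotypes, loci = q$sim$truth$adaptive_ids)
  gf <- gf_fit(g, q$sim$env, n_trees = 50, seed = 1)
  means <- vapply(c(0.5, 1, 2), function(d) {
    fut <- q$land$current
    fut$layers[[1]] <- fut$layers[[1]] + d
    fut$scenario <- "future"
    mean(gf_offset(gf, q$land$current, fut)$offset)
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-12))
  expect_gt(means[3], means[1])
})
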