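test_that("collinearity pruning respects the VIF and |r| ceilings", {
  set.seed(41)
  base <- matrix(rnorm(30 * 6), 30, 6)
  env <- as.data.frame(base)
  names(env) <- paste0("v", 1:6)
  # two perfectly correlated variables -> exactly one survives
  dup <- data.frame(a = env$v1, b = env$v1, c = env$v2)
  pr <- suppressWarnings(prune_collinear(dup))
  expect_equal(ncol(pr), 2)
  expect_true("c" %in% names(pr))
  # orthogonal variables all retained
  orth <- as.data.frame(qr.Q(qr(base))[, 1:4])
  expect_equal(ncol(prune_collinear(orth)), 4)
  # planted near-duplicates: survivors verified by recomputation
  env10 <- cbind(env,
                 d1 = env$v1 + rnorm(30, 0, 0.05),
                 d2 = env$v2 + rnorm(30, 0, 0.05),
                 d3 = env$v3 + rnorm(30, 0, 0.05))
  out <- prune_collinear(env10, vif_max = 10, r_max = 0.8)
  R <- abs(cor(out)); diag(R) <- 0
  expect_lte(max(R), 0.8)
  v <- diag(solve(cor(out)))
  expect_lte(max(v), 10)
  expect_gt(nrow(attr(out, "prune_report")), 0)
  # fewer sites than variables: correlation-only with warning
  expect_warning(prune_collinear(env10[1:5, ]), "VIF")
})

test_that("geographic and environmental distances are correct and invariant", {
  # quarter great circle
  d <- build_distances(data.frame(lat = c(0, 0), lon = c(0, 90)))
  expect_equal(unclass(d$geo)[1, 2], 10007.5, tolerance = 1)
  # identical points -> 0 km
  d0 <- build_distances(data.frame(lat = c(10, 10), lon = c(5, 5)))
  expect_equal(unclass(d0$geo)[1, 2], 0)
  # z-score invariance: doubling raw values leaves env distances unchanged
  set.seed(17)
  coords <- data.frame(lat = runif(8, 20, 25), lon = runif(8, 119, 122))
  env <- data.frame(x = rnorm(8), y = rnorm(8))
  d1 <- build_distances(coords, env)$env
  d2 <- build_distances(coords, env * 2)$env
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
  expect_error(build_distances(data.frame(lat = 91, lon = 0)), "out of range")
})

test_that("Mantel r, exact permutation p and type-I error behave", {
  set.seed(23)
  A <- as.matrix(dist(rnorm(10)))
  expect_equal(mantel(dist_matrix(A), dist_matrix(A), n_perm = 99)$r, 1)
  # exact enumeration over 4! relabelings vs direct oracle
  B <- as.matrix(dist(c(1, 3, 2, 4)))
  A4 <- as.matrix(dist(1:4))
  res <- mantel(dist_matrix(A4), dist_matrix(B), n_perm = "exact")
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  vb <- B[upper.tri(B)]
  rs <- apply(perms, 1, function(pm) {
    Ap <- A4[unlist(pm), unlist(pm)]
    cor(Ap[upper.tri(Ap)], vb)
  })
  expect_equal(res$p, mean(rs >= res$r - 1e-12), tolerance = 1e-12)
  expect_equal(nrow(perms), 24)
  # vegan agreement on the statistic
  vg <- vegan::mantel(as.dist(A4), as.dist(B), permutations = 0)
  expect_equal(res$r, vg$statistic, tolerance = 1e-10)
  expect_error(mantel(dist_matrix(matrix(0, 3, 3)), dist_matrix(A4[1:3, 1:3])),
               "zero variance")
})

test_that("Mantel type-I error is near nominal on independent matrices", {
  set.seed(29)
  rej <- 0; nrep <- 100
  for (r in 1:nrep) {
    a <- as.matrix(dist(rnorm(20)))
    b <- as.matrix(dist(rnorm(20)))
    rej <- rej + (mantel(dist_matrix(a), dist_matrix(b), n_perm = 99,
                         seed = r)$p <= 0.05)
  }
  expect_gte(rej / nrep, 0.005)
  expect_lte(rej / nrep, 0.12)
})

test_that("partial Mantel equals the partial-correlation oracle and its limits", {
  set.seed(37)
  n <- 12
  A <- as.matrix(dist(rnorm(n))); B <- as.matrix(dist(rnorm(n)))
  C <- as.matrix(dist(rnorm(n)))
  pm <- partial_mantel(dist_matrix(A), dist_matrix(B), dist_matrix(C),
                       n_perm = 99)
  ut <- upper.tri(A)
  rab <- cor(A[ut], B[ut]); rac <- cor(A[ut], C[ut]); rbc <- cor(B[ut], C[ut])
  oracle <- (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  expect_equal(pm$r, oracle, tolerance = 1e-10)
  # vacuous control (constant off-diagonal) = simple Mantel r
  K <- matrix(1, n, n); diag(K) <- 0
  pm0 <- partial_mantel(dist_matrix(A), dist_matrix(B), dist_matrix(K),
                        n_perm = 9)
  expect_equal(pm0$r, mantel(dist_matrix(A), dist_matrix(B), n_perm = 9)$r,
               tolerance = 1e-10)
  # b = control -> r ~ 0
  pmb <- partial_mantel(dist_matrix(A), dist_matrix(B), dist_matrix(B),
                        n_perm = 9)
  expect_lt(abs(pmb$r), 1e-8)
  # permutation p floor
  expect_gte(pm$p, 1 / 100)
})

test_that("reciprocal causal modeling is antisymmetric and recovers the generator", {
  set.seed(43)
  n <- 15
  coords <- data.frame(pop = paste0("P", 1:n), lat = runif(n, 22, 25),
                       lon = runif(n, 120, 122))
  envv <- data.frame(e1 = rnorm(n), e2 = rnorm(n))
  dl <- build_distances(coords, envv, categories = list(env = c("e1", "e2")))
  gen0 <- unclass(dl$env) * 0.02
  gend <- dist_matrix(gen0, labels = coords$pop, kind = "genetic")
  r <- rcm(gend, list(IBD = dl$geo, IBE = dl$env))
  expect_equal(r$support["IBD", "IBE"], -r$support["IBE", "IBD"],
               tolerance = 1e-12)
  expect_equal(diag(r$support), c(IBD = 0, IBE = 0))
  # single model: 1x1 zero matrix, nothing supported
  r1 <- rcm(gend, list(IBE = dl$env))
  expect_equal(unname(r1$support), matrix(0, 1, 1))
  expect_length(r1$fully_supported, 0)
  # generative recovery across seeds
  wins <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    coords2 <- data.frame(pop = paste0("P", 1:n), lat = runif(n, 22, 25),
                          lon = runif(n, 120, 122))
    env2 <- data.frame(e1 = rnorm(n), e2 = rnorm(n))
    d2 <- build_distances(coords2, env2,
                          categories = list(env = c("e1", "e2")))
    E <- unclass(d2$env)
    gen <- 0.05 + 0.03 * E / max(E)
    u <- rnorm(n, 0, 0.004)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gen[i, j] <- gen[j, i] <- gen[i, j] + u[i] + u[j] + rnorm(1, 0, 0.004)
    }
    diag(gen) <- 0
    gd <- dist_matrix(pmax((gen + t(gen)) / 2, 0), labels = coords2$pop,
                      kind = "genetic")
    rr <- rcm(gd, list(IBD = d2$geo, IBE = d2$env))
    wins <- wins + identical(rr$fully_supported, "IBE")
  }
  expect_gte(wins, 9)
})

test_that("MLPE reduces to OLS at rho = 0 and recovers generating slopes", {
  set.seed(47)
  n <- 12
  coords <- data.frame(pop = paste0("P", 1:n), lat = runif(n, 21, 25),
                       lon = runif(n, 119, 122))
  dl <- build_distances(coords)
  X <- unclass(dl$geo)
  Y <- 0.01 + 0.002 * X + as.matrix(dist(rnorm(n, 0, 0.1)))
  Y <- (Y + t(Y)) / 2; diag(Y) <- 0
  yd <- dist_matrix(Y, labels = coords$pop, kind = "genetic")
  m0 <- mlpe_fit(yd, dl$geo, rho = 0)
  ols <- lm(Y[upper.tri(Y)] ~ X[upper.tri(X)])
  expect_equal(unname(coef(m0)), unname(coef(ols)), tolerance = 1e-6)
  # identical predictors -> identical AIC
  mm <- mlpe_fit(yd, list(a = dl$geo, b = dl$geo))
  expect_equal(mm$ranking$AIC[1], mm$ranking$AIC[2], tolerance = 1e-8)
  # slope recovery + model separation under MLPE noise
  hits <- 0; sep <- 0; nrep <- 10
  for (s in 1:nrep) {
    set.seed(800 + s)
    npop <- 15
    co <- data.frame(pop = paste0("P", 1:npop), lat = runif(npop, 21, 25),
                     lon = runif(npop, 119, 122))
    dls <- build_distances(co, data.frame(e = rnorm(npop)),
                           categories = list(env = "e"))
    Xg <- unclass(dls$geo) / 100
    slope_true <- 0.05
    u <- rnorm(npop, 0, 0.02)
    Yg <- 0.1 + slope_true * Xg + outer(u, u, "+") +
      matrix(rnorm(npop^2, 0, 0.02), npop)
    Yg <- pmax((Yg + t(Yg)) / 2, 0); diag(Yg) <- 0
    ydm <- dist_matrix(Yg, labels = co$pop, kind = "genetic")
    fit <- mlpe_fit(ydm, list(geo = dls$geo, env = dls$env))
    mg <- fit$models$geo
    hits <- hits + (abs(coef(mg)[2] * 100 - slope_true) <
                      2 * mg$se[2] * 100 + 1e-9)
    rk <- fit$ranking
    sep <- sep + (rk$model[1] == "geo" && rk$dAIC[2] > 2)
  }
  expect_gte(hits, 8)
  expect_gte(sep, 9)
})

test_that("PCNM axes are orthogonal with non-increasing eigenvalues and match the oracle", {
  set.seed(53)
  coords <- data.frame(lat = runif(10, 22, 25), lon = runif(10, 120, 122))
  px <- pcnm_axes(coords)
  V <- px$vectors
  G <- crossprod(V)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_true(all(diff(px$values) <= 1e-10))
  expect_lte(ncol(px$half), ceiling(ncol(V) / 2))
  # direct double-centering eigen oracle
  D <- unclass(build_distances(coords)$geo)
  thr <- px$threshold
  Dt <- D; Dt[Dt > thr] <- 4 * thr
  A <- -0.5 * Dt^2
  n <- nrow(A)
  H <- diag(n) - matrix(1 / n, n, n)
  ev <- eigen(H %*% A %*% H, symmetric = TRUE)
  pos <- ev$values > 1e-8 * max(abs(ev$values))
  expect_equal(ncol(V), sum(pos))
  expect_equal(sort(px$values, decreasing = TRUE),
               sort(ev$values[pos], decreasing = TRUE), tolerance = 1e-6)
})

test_that("three-set RDA partition obeys the accounting identity and recovers structure", {
  set.seed(59)
  n <- 100
  A <- matrix(rnorm(n * 2), n); B <- matrix(rnorm(n * 2), n)
  C <- matrix(rnorm(n * 2), n)
  pures <- numeric(5); joints <- numeric(5)
  for (s in 1:5) {
    set.seed(900 + s)
    A <- matrix(rnorm(n * 2), n); B <- matrix(rnorm(n * 2), n)
    C <- matrix(rnorm(n * 2), n)
    Y <- A %*% matrix(c(1, 0.5, -0.3, 0.8), 2) + matrix(rnorm(n * 2, 0, 0.3), n)
    vp <- rda_partition(Y, A, B, C, n_perm = 99, seed = s)
    fr <- vp$fractions
    expect_equal(sum(fr), 1, tolerance = 1e-8)
    pures[s] <- fr[["pure_A"]]
    joints[s] <- max(abs(fr[c("joint_AB", "joint_BC", "joint_AC",
                              "joint_ABC")]))
    expect_equal(fr[["pure_A"]] + fr[["joint_AB"]] + fr[["joint_AC"]] +
                   fr[["joint_ABC"]], vp$r2_models[["A"]], tolerance = 1e-8)
  }
  expect_true(all(pures > 0.5))
  expect_true(all(joints < 0.05))
  # cross-check fractions against vegan::varpart
  set.seed(61)
  Y <- matrix(rnorm(n * 3), n)
  vp2 <- rda_partition(Y, A, B, C, n_perm = 49, seed = 1)
  vv <- vegan::varpart(Y, A, B, C)
  ind <- vv$part$indfract
  expect_equal(unname(vp2$fractions[c("pure_A", "pure_B", "pure_C")]),
               ind$Adj.R.square[1:3], tolerance = 1e-6)
})

test_that("niche overlap indices and the TSS threshold match direct arithmetic", {
  z <- matrix(c(0.2, 0.3, 0.1, 0.4), 2)
  ov <- niche_overlap(z, z)
  expect_equal(ov$D, 1); expect_equal(ov$I, 1)
  z1 <- matrix(c(1, 0), 1); z2 <- matrix(c(0, 1), 1)
  ov2 <- niche_overlap(z1, z2)
  expect_equal(ov2$D, 0); expect_equal(ov2$I, 0)
  ov3 <- niche_overlap(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1))
  expect_equal(ov3$D, 0.5)
  expect_equal(ov3$I, 1 - 0.5 * ((1 - sqrt(0.5))^2 + 0.5), tolerance = 1e-12)
  expect_error(niche_overlap(matrix(0, 2, 2), z), "all-zero")
  # equivalency p under identical generating distributions is not extreme
  set.seed(67)
  p1 <- cbind(rnorm(40), rnorm(40)); p2 <- cbind(rnorm(40), rnorm(40))
  k1 <- MASS::kde2d(p1[, 1], p1[, 2], n = 20,
                    lims = c(-4, 4, -4, 4))$z
  k2 <- MASS::kde2d(p2[, 1], p2[, 2], n = 20,
                    lims = c(-4, 4, -4, 4))$z
  ove <- niche_overlap(k1, k2, points1 = p1, points2 = p2, n_perm = 49,
                       seed = 2)
  expect_gte(ove$p_equivalency, 0.02)
})

test_that("TSS threshold maximizes sensitivity + specificity - 1", {
  sc <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  lb <- c(1, 1, 1, 0, 0, 0)
  ts <- tss_threshold(sc, lb)
  expect_equal(ts$tss, 1)
  expect_lte(ts$threshold, 0.7)
  # 8-point toy vs exhaustive scan
  sc2 <- c(0.1, 0.4, 0.35, 0.8, 0.6, 0.2, 0.7, 0.5)
  lb2 <- c(0, 0, 1, 1, 1, 0, 1, 0)
  ts2 <- tss_threshold(sc2, lb2)
  cands <- sort(unique(sc2))
  tss_all <- vapply(cands, function(th) {
    pred <- sc2 >= th
    sum(pred & lb2 == 1) / sum(lb2) + sum(!pred & lb2 == 0) / sum(!lb2) - 1
  }, numeric(1))
  expect_equal(ts2$tss, max(tss_all), tolerance = 1e-12)
  expect_equal(ts2$threshold, min(cands[tss_all >= max(tss_all) - 1e-12]))
  # labels independent of scores: TSS near zero on average
  set.seed(71)
  tss_null <- vapply(1:30, function(i) {
    tss_threshold(runif(200), sample(0:1, 200, TRUE))$tss
  }, numeric(1))
  expect_lt(mean(abs(tss_null)), 0.15)
  expect_error(tss_threshold(runif(5), rep(1, 5)), "both classes")
})
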