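#' End-to-end pipeline on a simulated study
#'
#' Runs the full analysis chain in dependency order on a synthetic study:
#' simulate -> filter -> structure (F_ST, PCA) -> association scans
#' (LFMM + PCA outliers, intersection) -> landscape model competition
#' (Mantel IBD/IBE, RCM, MLPE) -> genetic offsets (RONA, gradient forest,
#' GDM local/forward/reverse). Every stage writes its artifacts under
#' \code{out_dir} together with the resolved configuration and the seeds
#' used; a stage whose artifact files already exist is skipped unless
#' \code{resume = FALSE}, giving stage-level resume.
#'
#' @param config a \code{\link{sim_config}} describing the study.
#' @param out_dir output directory.
#' @param max_missing,min_maf SNP filters (defaults: missing rate < 0.4,
#'   MAF > 0.01).
#' @param K latent factors / principal components for the scans.
#' @param fdr_q q-value threshold (default 0.10).
#' @param n_perm_mantel Mantel permutations (default 999).
#' @param n_runs_lfmm LFMM bootstrap runs (default 5).
#' @param resume skip stages whose outputs already exist.
#' @return A list of stage results (invisibly written to disk as well):
#'   \code{sim}, \code{filtered}, \code{fst}, \code{pca}, \code{lfmm},
#'   \code{pcadapt}, \code{adaptive}, \code{models}, \code{offsets}.
#' @export
run_pipeline <- function(config, out_dir, max_missing = 0.4,
                         min_maf = 0.01, K = 2, fdr_q = 0.10,
                         n_perm_mantel = 999, n_runs_lfmm = 5,
                         resume = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline start; seed=%d", config$seed)
  stage <- function(name, files, fun) {
    paths <- file.path(out_dir, files)
    if (resume && all(file.exists(paths))) {
      logf("stage %s: outputs present, skipped", name)
      return(NULL)
    }
    logf("stage %s: running", name)
    res <- tryCatch(fun(), error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed (see %s): %s", name,
                   log_path, conditionMessage(e)), call. = FALSE)
    })
    res
  }

  land <- simulate_landscape(config)
  sim <- simulate_genotypes(config, land$current, land$future)
  stage("simulate", "genotypes.vcf",
        function() write_simulation(sim, land, out_dir))

  filtered <- filter_snps(sim$genotypes, max_missing, min_maf)
  rep <- attr(filtered, "filter_report")
  stage("filter", "filter_report.json", function() {
    jsonlite::write_json(rep, file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  logf("filter: %d -> %d loci", rep$n_input, rep$n_retained)

  fst <- weir_cockerham_fst(filtered)
  pca <- genotype_pca(filtered, n_components = K + 3)
  stage("structure", c("fst_per_locus.csv", "fst_pairwise.csv"), function() {
    utils::write.csv(fst$per_locus,
                     file.path(out_dir, "fst_per_locus.csv"),
                     row.names = FALSE)
    utils::write.csv(fst$pairwise, file.path(out_dir, "fst_pairwise.csv"))
    nw <- neighbor_joining(nei_distance(allele_freqs(filtered,
                                                     by_pop = TRUE)))
    writeLines(nw, file.path(out_dir, "nj_tree.nwk"))
  })
  logf("structure: multilocus FST=%.4f", fst$multilocus)

  lf <- fit_lfmm(filtered, sim$env, K = K, n_runs = n_runs_lfmm,
                 seed = config$seed)
  pc <- pcadapt_scan(filtered, K = K)
  pc_hits <- outlier_set(rownames(pc$q)[pc$q[, 1] < fdr_q],
                         method = "pcadapt", threshold = fdr_q)
  adaptive <- intersect_outliers(lf, list(pc_hits), q_threshold = fdr_q)
  stage("scan", "association.csv", function() {
    assoc <- data.frame(locus = rownames(lf$p))
    for (v in colnames(lf$p)) {
      assoc[[paste0("z_", v)]] <- lf$z[, v]
      assoc[[paste0("p_", v)]] <- lf$p[, v]
      assoc[[paste0("q_", v)]] <- lf$q[, v]
    }
    utils::write.csv(assoc, file.path(out_dir, "association.csv"),
                     row.names = FALSE)
    writeLines(adaptive$ids, file.path(out_dir, "adaptive_loci.txt"))
    write_outlier_bed(filtered, adaptive,
                      file.path(out_dir, "adaptive_loci.bed"))
  })
  logf("scan: %d LFMM hits, %d pcadapt hits, %d intersection",
       sum(apply(lf$q < fdr_q, 1, any)), length(pc_hits$ids),
       length(adaptive$ids))

  # landscape model competition on population distance matrices
  pop_coords <- unique(sim$genotypes$individuals[c("pop", "lat", "lon")])
  dists <- build_distances(pop_coords,
                           env = sim$env[match(pop_coords$pop,
                                               sim$env$pop),
                                         setdiff(names(sim$env), "pop")],
                           categories = list(climate =
                             setdiff(names(sim$env), "pop")))
  gen_lin <- dist_matrix(linearized_fst(pmax(fst$pairwise, 0)),
                         kind = "genetic")
  models <- list(IBD = dists$geo, IBE = dists$climate)
  mant <- lapply(models, function(m)
    mantel(gen_lin, m, n_perm = n_perm_mantel, seed = config$seed))
  rcm_res <- rcm(gen_lin, models)
  mlpe_res <- mlpe_fit(gen_lin, models)
  stage("models", "model_ranking.csv", function() {
    utils::write.csv(mlpe_res$ranking,
                     file.path(out_dir, "model_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(rcm_res$support, file.path(out_dir, "rcm_support.csv"))
  })
  logf("models: best MLPE = %s; RCM fully supported = %s",
       mlpe_res$ranking$model[1],
       paste(rcm_res$fully_supported, collapse = ","))

  # offsets on the adaptive loci (fall back to top-q loci if empty)
  adaptive_idx <- match(adaptive$ids, colnames(filtered$geno))
  if (length(adaptive_idx) < 2 || anyNA(adaptive_idx)) {
    ord <- order(apply(lf$q, 1, min))
    adaptive_idx <- ord[seq_len(min(20, length(ord)))]
  }
  g_adapt <- subset_genotypes(filtered, loci = adaptive_idx)
  env_vars <- setdiff(names(sim$env), "pop")
  fut_env <- sim$env
  for (j in seq_along(env_vars)) {
    fut_env[[env_vars[j]]] <- fut_env[[env_vars[j]]] +
      config$future_delta[j]
  }
  sig <- stats::setNames(lapply(env_vars, function(v) {
    rownames(lf$q)[lf$q[, v] < fdr_q & rownames(lf$q) %in%
                     colnames(g_adapt$geno)]
  }), env_vars)
  sig <- sig[vapply(sig, length, integer(1)) > 0]
  ron <- if (length(sig) > 0) rona(g_adapt, sim$env, fut_env, sig) else NULL
  gf <- gf_fit(g_adapt, sim$env, n_trees = 100, seed = config$seed)
  gf_off <- gf_offset(gf, land$current, land$future)
  pop_dis <- unclass_dist(gen_lin)
  pop_dis <- pop_dis / (max(pop_dis) * 1.05 + 1e-12)
  gdm <- gdm_fit(dist_matrix(pop_dis, kind = "genetic",
                             labels = rownames(fst$pairwise)),
                 sim$env, coords = pop_coords)
  gdm_off <- gdm_offsets(gdm, land$current, land$future)
  stage("offset", "offsets.csv", function() {
    utils::write.csv(as.data.frame(gdm_off),
                     file.path(out_dir, "offsets.csv"), row.names = FALSE)
    utils::write.csv(gf_off, file.path(out_dir, "gf_offset.csv"),
                     row.names = FALSE)
    if (!is.null(ron)) {
      utils::write.csv(ron$rona, file.path(out_dir, "rona.csv"))
    }
    utils::write.csv(offsets_rgb(gdm_off),
                     file.path(out_dir, "offsets_rgb.csv"),
                     row.names = FALSE)
  })
  logf("offset: mean local=%.4f forward=%.4f reverse=%.4f",
       mean(gdm_off$local), mean(gdm_off$forward), mean(gdm_off$reverse))
  logf("pipeline done")

  invisible(list(sim = sim, landscape = land, filtered = filtered,
                 fst = fst, pca = pca, lfmm = lf, pcadapt = pc,
                 adaptive = adaptive, mantel = mant, rcm = rcm_res,
                 mlpe = mlpe_res, rona = ron, gf = gf,
                 gf_offset = gf_off, gdm = gdm, gdm_offsets = gdm_off))
}
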