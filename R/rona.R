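#' Risk of non-adaptedness (RONA)
#'
#' For each significant locus and environmental variable, regresses
#' population allele frequency on the variable across populations (ordinary
#' least squares); the per-locus RONA at population j is the absolute
#' change in fitted frequency between current and future conditions,
#' |slope| * |delta e_j|. The population-level RONA for a variable is the
#' weighted mean of per-locus RONA with weights R-squared of the per-locus
#' regressions. Variables are ranked by their number of significant loci
#' and the top three flagged.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param env populations x variables data.frame of current conditions
#'   (with a \code{pop} column or rownames matching population labels).
#' @param future_env same shape, future conditions.
#' @param sig_loci named list: for each variable, the locus ids significant
#'   for it (e.g. from \code{\link{fit_lfmm}} at q < 0.10). Variables absent
#'   or empty are excluded with a warning.
#' @return An object of class \code{rona_result}: \code{rona}
#'   (populations x variables weighted RONA), \code{per_locus} (data.frame
#'   with slope, intercept, r2 and mean per-locus RONA), \code{ranking}
#'   (variable, n_sig_loci, top3 flag).
#' @export
rona <- function(g, env, future_env, sig_loci) {
  stopifnot(inherits(g, "genotype_matrix"))
  pf <- allele_freqs(g, by_pop = TRUE)
  env <- as.data.frame(env); future_env <- as.data.frame(future_env)
  pops <- rownames(pf)
  row_of <- function(tab) {
    if (!is.null(tab$pop)) {
      idx <- match(pops, tab$pop)
      tab <- tab[idx, setdiff(names(tab), "pop"), drop = FALSE]
    } else {
      tab <- tab[match(pops, rownames(tab)), , drop = FALSE]
    }
    tab
  }
  env <- row_of(env); future_env <- row_of(future_env)
  vars <- names(sig_loci)
  empty <- vapply(sig_loci, length, integer(1)) == 0
  if (any(empty)) {
    warning("no significant loci for: ", paste(vars[empty], collapse = ", "))
    vars <- vars[!empty]
  }
  if (length(vars) == 0) stop("no variable has significant loci")
  R <- matrix(0, length(pops), length(vars),
              dimnames = list(pops, vars))
  per_locus <- list()
  for (v in vars) {
    e_cur <- env[[v]]; e_fut <- future_env[[v]]
    de <- abs(e_fut - e_cur)
    loci <- intersect(sig_loci[[v]], colnames(pf))
    num <- rep(0, length(pops)); den <- 0
    for (l in loci) {
      y <- pf[, l]
      ok <- is.finite(y)
      fit <- stats::lm(y[ok] ~ e_cur[ok])
      slope <- stats::coef(fit)[2]
      r2 <- summary(fit)$r.squared
      rl <- abs(slope) * de
      num <- num + r2 * rl
      den <- den + r2
      per_locus[[paste(v, l, sep = ":")]] <-
        data.frame(variable = v, locus = l,
                   slope = unname(slope),
                   intercept = unname(stats::coef(fit)[1]),
                   r2 = r2, mean_rona = mean(rl))
    }
    R[, v] <- if (den > 0) num / den else 0
  }
  ranking <- data.frame(variable = vars,
                        n_sig_loci = vapply(sig_loci[vars], length,
                                            integer(1)))
  ranking <- ranking[order(-ranking$n_sig_loci), ]
  ranking$top3 <- seq_len(nrow(ranking)) <= 3
  structure(list(rona = R, per_locus = do.call(rbind, per_locus),
                 ranking = ranking),
            class = "rona_result")
}

#' @export
print.rona_result <- function(x, ...) {
  cat(sprintf("RONA over %d populations x %d variables\n",
              nrow(x$rona), ncol(x$rona)))
  cat("  population means per variable:\n")
  print(round(colMeans(x$rona), 4))
  invisible(x)
}
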