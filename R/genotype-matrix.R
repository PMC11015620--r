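#' Genotype matrix container
#'
#' Bundles a diploid biallelic dosage matrix (individuals x loci, values
#' 0/1/2 counting alternate alleles, \code{NA} for missing) with locus
#' metadata, individual ids, population labels and coordinates.
#'
#' @param geno integer matrix, individuals in rows, loci in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}; one row per locus. Generated automatically when
#'   omitted.
#' @param individuals data.frame with columns \code{id}, \code{pop},
#'   \code{lat}, \code{lon}; one row per individual. Generated automatically
#'   when omitted (single population, missing coordinates).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(geno, loci = NULL, individuals = NULL) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotype entries must be 0, 1, 2 or NA")
  }
  storage.mode(geno) <- "integer"
  n_ind <- nrow(geno)
  n_loc <- ncol(geno)
  if (is.null(loci)) {
    loci <- data.frame(chrom = "1", pos = seq_len(n_loc) * 1000L,
                       ref = "A", alt = "T")
  }
  if (is.null(individuals)) {
    individuals <- data.frame(id = sprintf("ind%03d", seq_len(n_ind)),
                              pop = "pop1", lat = NA_real_, lon = NA_real_)
  }
  stopifnot(nrow(loci) == n_loc, nrow(individuals) == n_ind)
  if (anyNA(individuals$pop)) stop("every individual needs a population label")
  loci$id <- paste0(loci$chrom, ":", loci$pos)
  # locus order is free (scans are order-invariant); ids must be unique
  if (anyDuplicated(loci$id)) stop("duplicated locus (chrom, pos)")
  rownames(geno) <- individuals$id
  colnames(geno) <- loci$id
  structure(list(geno = geno, loci = loci, individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$individuals$pop))))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset loci and/or individuals of a genotype matrix
#'
#' @param g a \code{genotype_matrix}.
#' @param ind,loci integer or logical index vectors (default: keep all).
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(g, ind = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(ind)) ind <- seq_len(nrow(g$geno))
  if (is.null(loci)) loci <- seq_len(ncol(g$geno))
  genotype_matrix(g$geno[ind, loci, drop = FALSE],
                  g$loci[loci, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                  g$individuals[ind, , drop = FALSE])
}

#' Per-locus alternate-allele frequencies
#'
#' @param g a \code{genotype_matrix}.
#' @param by_pop if \code{TRUE}, return a populations x loci matrix;
#'   otherwise a vector over loci. Missing genotypes are excluded per locus
#'   (and per population).
#' @return Numeric vector or matrix of allele frequencies; \code{NaN} where a
#'   population has no genotyped individual at a locus.
#' @export
allele_freqs <- function(g, by_pop = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!by_pop) {
    return(colMeans(g$geno, na.rm = TRUE) / 2)
  }
  pops <- unique(g$individuals$pop)
  out <- matrix(NA_real_, length(pops), ncol(g$geno),
                dimnames = list(pops, colnames(g$geno)))
  for (p in pops) {
    rows <- g$individuals$pop == p
    out[p, ] <- colMeans(g$geno[rows, , drop = FALSE], na.rm = TRUE) / 2
  }
  out
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing entry by the locus mean dosage (the convention used
#' before PCA and the association scans). Loci that are entirely missing
#' become all-zero columns.
#'
#' @param g a \code{genotype_matrix} or plain dosage matrix.
#' @return A numeric matrix with no missing values.
#' @export
impute_mean <- function(g) {
  m <- if (inherits(g, "genotype_matrix")) g$geno else as.matrix(g)
  m <- apply(m, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    col
  })
  m
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Removes loci whose missing fraction is \code{>= max_missing} or whose
#' minor allele frequency is \code{<= min_maf}. Defaults reproduce the usual
#' RAD-seq filters (missing rate < 0.4, MAF > 0.01).
#'
#' @param raw a \code{genotype_matrix} of biallelic SNPs.
#' @param max_missing loci with missing fraction at or above this are dropped.
#' @param min_maf loci with minor allele frequency at or below this are
#'   dropped (MAF computed on non-missing genotypes).
#' @return The filtered \code{genotype_matrix}, with an attribute
#'   \code{"filter_report"}: counts removed by each rule.
#' @export
filter_snps <- function(raw, max_missing = 0.4, min_maf = 0.01) {
  stopifnot(inherits(raw, "genotype_matrix"))
  miss <- colMeans(is.na(raw$geno))
  p <- colMeans(raw$geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  drop_miss <- miss >= max_missing
  # min_maf = 0 disables the MAF rule (otherwise maf <= threshold drops)
  drop_maf <- !drop_miss & min_maf > 0 & maf <= min_maf
  keep <- !(drop_miss | drop_maf)
  if (!any(keep)) stop("all loci removed by filters; nothing retained")
  out <- subset_genotypes(raw, loci = which(keep))
  attr(out, "filter_report") <- list(
    n_input = ncol(raw$geno),
    removed_missing = sum(drop_miss),
    removed_maf = sum(drop_maf),
    n_retained = sum(keep))
  out
}
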