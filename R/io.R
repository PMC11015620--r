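#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x with GT fields (via \pkg{vcfR}); phased and unphased
#' genotypes are treated identically, half-calls and \code{./.} become
#' missing. Multi-allelic records are rejected.
#'
#' @param path VCF file (plain text or gzipped).
#' @param samples optional data.frame (columns \code{id}, \code{pop},
#'   \code{lat}, \code{lon}) attaching population labels and coordinates;
#'   matched on sample id.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) stop("multi-allelic records present; split them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    s <- gsub("\\|", "/", s)
    out <- rep(NA_integer_, length(s))
    out[s == "0/0"] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s == "1/1"] <- 2L
    out
  }
  geno <- t(apply(gt, 1, count_alt))        # loci x ind -> transpose below
  geno <- t(geno)
  colnames(geno) <- NULL
  loci <- data.frame(chrom = vcfR::getCHROM(v),
                     pos = as.integer(vcfR::getPOS(v)),
                     ref = vcfR::getREF(v), alt = alt)
  ids <- colnames(gt)
  ind <- data.frame(id = ids, pop = "pop1", lat = NA_real_, lon = NA_real_)
  if (!is.null(samples)) {
    m <- match(ids, samples$id)
    if (anyNA(m)) stop("samples table missing ids: ",
                       paste(ids[is.na(m)], collapse = ", "))
    ind <- data.frame(id = ids, pop = samples$pop[m],
                      lat = samples$lat[m], lon = samples$lon[m])
  }
  genotype_matrix(geno, loci, ind)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Biallelic SNP records with a GT field; missing genotypes as
#' \code{./.}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=adaptscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", g$individuals$id),
                     collapse = "\t")), con)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (l in seq_len(ncol(g$geno))) {
    gvec <- g$geno[, l]
    gs <- ifelse(is.na(gvec), "./.", gt_str[as.character(gvec)])
    writeLines(paste(c(g$loci$chrom[l], g$loci$pos[l], g$loci$id[l],
                       g$loci$ref[l], g$loci$alt[l], ".", "PASS", ".",
                       "GT", gs), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the simulated study to disk
#'
#' Emits the standard interchange set: a VCF 4.2 of genotypes, a samples
#' CSV (id, population, lat, lon), a population x variable environment CSV,
#' one ESRI ASCII grid per layer and scenario, and a ground-truth JSON
#' sidecar.
#'
#' @param sim output of \code{\link{simulate_genotypes}}.
#' @param landscape output of \code{\link{simulate_landscape}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  utils::write.csv(sim$genotypes$individuals,
                   file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(sim$env, file.path(dir, "environment.csv"),
                   row.names = FALSE)
  for (scen in c("current", "future")) {
    for (v in names(landscape[[scen]]$layers)) {
      write_ascii_grid(landscape[[scen]], v,
                       file.path(dir, sprintf("%s_%s.asc", scen, v)))
    }
  }
  truth <- sim$truth
  truth$pop_freq <- NULL                     # large; not needed downstream
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a labeled distance matrix as CSV
#'
#' @param d a \code{\link{dist_matrix}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dist_csv <- function(d, path) {
  m <- unclass_dist(d)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Read a labeled distance matrix from CSV
#'
#' @param path CSV with label header row and first column.
#' @param kind tag for the resulting \code{\link{dist_matrix}}.
#' @return A \code{dist_matrix}.
#' @export
read_dist_csv <- function(path, kind = "resistance") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  dist_matrix(m, kind = kind)
}

#' Export outlier loci as BED intervals
#'
#' VCF positions are 1-based; BED is 0-based half-open, so a SNP at
#' position p becomes the interval [p-1, p).
#'
#' @param g a \code{\link{genotype_matrix}} providing locus coordinates.
#' @param set an \code{\link{outlier_set}}.
#' @param path output BED file.
#' @return the path, invisibly.
#' @export
write_outlier_bed <- function(g, set, path) {
  idx <- match(set$ids, g$loci$id)
  idx <- idx[!is.na(idx)]
  bed <- data.frame(chrom = g$loci$chrom[idx],
                    start = g$loci$pos[idx] - 1L,
                    end = g$loci$pos[idx])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an external outlier set (one locus id per line)
#'
#' @param path text file of locus ids.
#' @param method tag (default \code{"external"}).
#' @return An \code{\link{outlier_set}}.
#' @export
read_outlier_ids <- function(path, method = "external") {
  outlier_set(readLines(path), method = method)
}
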