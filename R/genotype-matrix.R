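## The genotype matrix: sites x samples, the substrate of every statistic.

GENO_CODES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
POP_LEVELS <- c("wild", "landrace", "elite")

#' Construct a genotype matrix
#'
#' The central container of the package: biallelic SNP sites (rows) by
#' samples (columns), with per-site coordinates and alleles and a
#' population label per sample.  Genotypes are coded `0` (homozygous
#' reference), `1` (heterozygous), `2` (homozygous alternate) and `NA`
#' (missing).
#'
#' @param chrom character vector of chromosome ids, one per site
#' @param pos integer vector of 1-based positions (VCF convention);
#'   strictly increasing within a chromosome
#' @param ref,alt single-base reference / alternate alleles (A/C/G/T)
#' @param geno integer matrix, sites x samples, codes 0/1/2/NA
#' @param samples character vector of sample ids (column names)
#' @param pops character vector of population labels, parallel to
#'   `samples`; any label set is allowed but the canonical groups are
#'   `wild`, `landrace`, `elite`
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, samples, pops) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_site <- length(pos)
  if (length(chrom) != n_site || length(ref) != n_site || length(alt) != n_site)
    abort("genotype_matrix(): per-site vectors have unequal lengths")
  if (nrow(geno) != n_site || ncol(geno) != length(samples))
    abort("genotype_matrix(): geno must be %d sites x %d samples", n_site, length(samples))
  if (length(pops) != length(samples))
    abort("genotype_matrix(): one population label per sample required")
  if (n_site > 0) {
    bad <- geno[!is.na(geno)]
    if (length(bad) && !all(bad %in% 0:2))
      abort("genotype_matrix(): genotype codes must be 0, 1, 2 or NA")
    ord <- order(chrom, pos)
    if (is.unsorted(ord, strictly = FALSE) || any(diff(ord) != 1)) {
      chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
      geno <- geno[ord, , drop = FALSE]
    }
    dup <- unlist(tapply(pos, chrom, function(p) c(FALSE, diff(p) <= 0)),
                  use.names = FALSE)
    if (any(dup))
      abort("genotype_matrix(): positions must be strictly increasing within a chromosome")
    if (!all(ref %in% c("A", "C", "G", "T")) || !all(alt %in% c("A", "C", "G", "T")))
      abort("genotype_matrix(): alleles must be single bases A/C/G/T")
  }
  colnames(geno) <- samples
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         geno = geno, samples = as.character(samples),
         pops = stats::setNames(as.character(pops), samples)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n",
              n_sites(x), length(x$samples)))
  if (length(x$samples)) {
    tab <- table(x$pops)
    cat("  populations:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (n_sites(x)) {
    for (ch in unique(x$chrom)) {
      p <- x$pos[x$chrom == ch]
      cat(sprintf("  %s: %d sites in [%d, %d]\n", ch, length(p), min(p), max(p)))
    }
  }
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset sites of a genotype matrix
#' @param gm a `genotype_matrix`
#' @param i logical or integer site index
#' @return a `genotype_matrix`
#' @export
subset_sites <- function(gm, i) {
  genotype_matrix(gm$chrom[i], gm$pos[i], gm$ref[i], gm$alt[i],
                  gm$geno[i, , drop = FALSE], gm$samples, gm$pops)
}

#' Sample ids belonging to given population labels
#' @param gm a `genotype_matrix`
#' @param groups character vector of population labels
#' @return character vector of sample ids
#' @export
samples_of <- function(gm, groups) {
  unknown <- setdiff(groups, unique(gm$pops))
  if (length(unknown))
    abort("unknown population label(s): %s", paste(unknown, collapse = ", "))
  gm$samples[gm$pops %in% groups]
}

#' Inbred haplotype encoding of a genotype matrix
#'
#' Selfing lines are nearly fully homozygous, so each line contributes a
#' single haplotype: homozygous reference maps to 0, homozygous
#' alternate to 1, and residual heterozygous calls are treated as
#' missing (NA) for diversity and LD statistics.
#'
#' @param gm a `genotype_matrix`
#' @param samples optional subset of sample ids (default: all)
#' @return integer matrix, sites x haplotypes, values 0/1/NA
#' @export
haplotypes <- function(gm, samples = NULL) {
  g <- gm$geno
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  h <- g
  h[h == 1L] <- NA_integer_
  h[h == 2L] <- 1L
  h
}
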