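## VCF / TSV input-output and the site-level QC filters that produce the
## analysis-ready genotype matrix.

#' Read a population assignment table
#'
#' Two-column TSV without header: sample id, population label.
#'
#' @param path file path
#' @return named character vector of labels, names = sample ids
#' @export
read_populations <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "group"),
                          colClasses = "character")
  stats::setNames(tb$group, tb$sample)
}

## Map a vector of VCF GT strings to codes 0/1/2/NA (biallelic sites).
gt_to_code <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("\\|", "/", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt == "1/1"] <- 2L
  out
}

code_to_gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Read a multi-sample VCF into a genotype matrix and an indel set
#'
#' Biallelic SNP records become the [genotype_matrix()]; biallelic
#' length-changing records with a net length change of 1-5 bp become
#' the indel set; multi-allelic records and indels longer than 5 bp are
#' skipped and counted.
#'
#' @param path VCF file (plain text or bgzip)
#' @param populations named character vector from [read_populations()],
#'   or a path to the population TSV
#' @param max_indel largest absolute length change retained (bp)
#' @return list with `snps` (a `genotype_matrix`), `indels` (data frame
#'   with per-record coordinates, alleles, `dlen`, and a genotype-code
#'   matrix in `geno`), and `n_skipped`
#' @export
read_vcf <- function(path, populations, max_indel = 5L) {
  if (is.character(populations) && length(populations) == 1 &&
      file.exists(populations)) {
    populations <- read_populations(populations)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  missing_pop <- setdiff(samples, names(populations))
  if (length(missing_pop))
    abort("sample(s) missing from the population table: %s",
          paste(missing_pop, collapse = ", "))
  pops <- unname(populations[samples])

  if (nrow(fix) == 0) {
    empty <- genotype_matrix(character(0), integer(0), character(0),
                             character(0), matrix(0L, 0, length(samples)),
                             samples, pops)
    return(list(snps = empty,
                indels = data.frame(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    dlen = integer(0)),
                n_skipped = 0L))
  }

  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  dlen <- nchar(alt) - nchar(ref)
  is_snp <- !multi & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  is_indel <- !multi & !is_snp & dlen != 0 & abs(dlen) <= max_indel
  skipped <- !is_snp & !is_indel
  n_skipped <- sum(skipped)
  if (n_skipped)
    message(sprintf("read_vcf: skipped %d record(s) (multi-allelic, MNP or indel > %d bp)",
                    n_skipped, max_indel))

  gt <- v@gt[, -1, drop = FALSE]
  codes <- apply(gt, 2, gt_to_code)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(fix))

  gm <- genotype_matrix(chrom[is_snp], pos[is_snp], ref[is_snp], alt[is_snp],
                        codes[is_snp, , drop = FALSE], samples, pops)
  ind <- data.frame(chrom = chrom[is_indel], pos = pos[is_indel],
                    ref = ref[is_indel], alt = alt[is_indel],
                    dlen = dlen[is_indel])
  ind_geno <- codes[is_indel, , drop = FALSE]
  colnames(ind_geno) <- samples
  ind$geno <- ind_geno
  list(snps = gm, indels = ind, n_skipped = n_skipped)
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits a minimal GT-only VCF with deterministic bytes (no date stamp),
#' so fixed-seed simulations round-trip identically.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popsweep",
               sprintf("##contig=<ID=%s>", unique(gm$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  if (n_sites(gm)) {
    gt <- matrix(code_to_gt[as.character(gm$geno)], nrow = n_sites(gm))
    gt[is.na(gt)] <- "./."
    body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                  "GT", sep = "\t")
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Site-filter thresholds
#'
#' Defaults are the published pipeline's gates: aggregate depth strictly
#' between 50x and 3000x, consensus quality strictly above 15, copy
#' number strictly below 1.5, and removal of sites whose heterozygote
#' ratio (heterozygous / non-missing genotypes) or missing ratio
#' (missing / all genotypes) exceeds 0.88.  All thresholds are strict:
#' a value exactly at a bound fails.
#'
#' @param depth_min,depth_max aggregate depth gates (x)
#' @param qual_min consensus quality gate
#' @param cn_max copy-number gate
#' @param het_ratio_max,miss_ratio_max per-site genotype-ratio gates
#' @return an object of class `filter_config`
#' @export
filter_config <- function(depth_min = 50, depth_max = 3000, qual_min = 15,
                          cn_max = 1.5, het_ratio_max = 0.88,
                          miss_ratio_max = 0.88) {
  if (depth_min >= depth_max) abort("filter_config(): depth_min must be < depth_max")
  if (het_ratio_max < 0 || het_ratio_max > 1 ||
      miss_ratio_max < 0 || miss_ratio_max > 1)
    abort("filter_config(): ratio thresholds must lie in [0, 1]")
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 qual_min = qual_min, cn_max = cn_max,
                 het_ratio_max = het_ratio_max,
                 miss_ratio_max = miss_ratio_max),
            class = "filter_config")
}

#' Read a per-site QC table
#'
#' TSV with header columns chrom, pos, depth, qual, cn.
#'
#' @param path file path
#' @return data frame
#' @export
read_site_qc <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(chrom = "character"))
}

#' Apply aggregate depth / quality / copy-number site filters
#'
#' Retains exactly the sites with `depth_min < depth < depth_max`,
#' `qual > qual_min` and `cn < cn_max` (strict inequalities throughout);
#' site order is preserved.
#'
#' @param gm a [genotype_matrix()]
#' @param qc data frame with columns chrom, pos, depth, qual, cn
#'   covering every site of `gm`
#' @param cfg a [filter_config()]
#' @return the filtered `genotype_matrix`
#' @export
apply_site_qc <- function(gm, qc, cfg = filter_config()) {
  key_gm <- paste(gm$chrom, gm$pos)
  key_qc <- paste(qc$chrom, qc$pos)
  idx <- match(key_gm, key_qc)
  if (anyNA(idx)) {
    miss <- key_gm[is.na(idx)][1]
    abort("apply_site_qc(): no QC row for site %s", miss)
  }
  qc <- qc[idx, ]
  keep <- qc$depth > cfg$depth_min & qc$depth < cfg$depth_max &
    qc$qual > cfg$qual_min & qc$cn < cfg$cn_max
  subset_sites(gm, keep)
}

#' Remove sites with excess heterozygosity or missingness
#'
#' A site is removed when its heterozygote ratio (heterozygous calls
#' over non-missing calls) or its missing ratio (missing calls over all
#' samples) is strictly greater than the configured threshold.
#'
#' @param gm a [genotype_matrix()]
#' @param cfg a [filter_config()]
#' @return the filtered `genotype_matrix`
#' @export
filter_het_missing <- function(gm, cfg = filter_config()) {
  if (n_sites(gm) == 0) return(gm)
  g <- gm$geno
  n_samp <- ncol(g)
  n_miss <- rowSums(is.na(g))
  n_obs <- n_samp - n_miss
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  het_ratio <- ifelse(n_obs > 0, n_het / n_obs, 0)
  miss_ratio <- n_miss / n_samp
  keep <- het_ratio <= cfg$het_ratio_max & miss_ratio <= cfg$miss_ratio_max
  subset_sites(gm, keep)
}
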