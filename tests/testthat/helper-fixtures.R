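# Fixtures and independent brute-force oracles shared across tests.

# Build a genotype_matrix from a plain site x sample code matrix
gm_fixture <- function(codes, pops = NULL, chrom = "chr1", pos = NULL,
                       ref = NULL, alt = NULL) {
  codes <- as.matrix(codes)
  n_site <- nrow(codes); n_samp <- ncol(codes)
  samples <- sprintf("s%02d", seq_len(n_samp))
  if (is.null(pops)) pops <- rep("wild", n_samp)
  if (is.null(pos)) pos <- seq_len(n_site) * 10L
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("T", n_site)
  genotype_matrix(rep(chrom, n_site), pos, ref, alt, codes, samples, pops)
}

# All-pairs brute force for theta-pi: mean pairwise difference per site,
# pairwise deletion of missing data
bf_theta_pi <- function(h, L) {
  n <- ncol(h)
  total <- 0
  any_pair <- FALSE
  for (s in seq_len(nrow(h))) {
    diffs <- 0; pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- h[s, i]; b <- h[s, j]
      if (!is.na(a) && !is.na(b)) {
        pairs <- pairs + 1
        diffs <- diffs + (a != b)
      }
    }
    if (pairs > 0) {
      any_pair <- TRUE
      total <- total + diffs / pairs
    }
  }
  if (nrow(h) > 0 && !any_pair) return(NA_real_)
  total / L
}

# r^2 from an explicit 2x2 haplotype count table (nAB, nAb, naB, nab)
bf_r2 <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / n
  pB <- (nAB + naB) / n
  D <- nAB / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Hudson Fst from allele counts at a single site (frequency moments)
bf_fst_one_site <- function(n1_alt, n1_tot, n2_alt, n2_tot) {
  p1 <- n1_alt / n1_tot; p2 <- n2_alt / n2_tot
  hw <- (n1_tot / (n1_tot - 1) * 2 * p1 * (1 - p1) +
           n2_tot / (n2_tot - 1) * 2 * p2 * (1 - p2)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - hw / hb
}

# A toy two-gene model: g1 on the plus strand, g2 on the minus strand,
# each with two CDS exons, a 10 bp intron and 10 bp UTRs.
# g1: span 101-166; UTR5 101-110, CDS 111-128 + 139-156, intron 129-138,
#     UTR3 157-166.  Coding sequence = the 12 codons of `g1_codons`.
# g2: span 301-366, mirrored (5' UTR at the high end).
g1_codons <- c("ATG", "GCT", "GCC", "TGG", "AAA", "CCC",
               "GGG", "TTT", "CTT", "GAG", "ACA", "TAA")
g2_codons <- c("ATG", "CCA", "CCG", "TGG", "AAG", "GTA",
               "GGT", "TCT", "CTG", "GAA", "ACT", "TAA")

toy_models <- function() {
  feat <- function(gene, chrom, strand, type, start, end)
    data.frame(type = type, start = start, end = end, gene = gene,
               chrom = chrom, strand = strand)
  g1 <- rbind(
    feat("g1", "chr1", "+", "gene", 101, 166),
    feat("g1", "chr1", "+", "mRNA", 101, 166),
    feat("g1", "chr1", "+", "exon", 101, 128),
    feat("g1", "chr1", "+", "exon", 139, 166),
    feat("g1", "chr1", "+", "five_prime_UTR", 101, 110),
    feat("g1", "chr1", "+", "CDS", 111, 128),
    feat("g1", "chr1", "+", "CDS", 139, 156),
    feat("g1", "chr1", "+", "three_prime_UTR", 157, 166))
  g2 <- rbind(
    feat("g2", "chr1", "-", "gene", 301, 366),
    feat("g2", "chr1", "-", "mRNA", 301, 366),
    feat("g2", "chr1", "-", "exon", 301, 328),
    feat("g2", "chr1", "-", "exon", 339, 366),
    feat("g2", "chr1", "-", "three_prime_UTR", 301, 310),
    feat("g2", "chr1", "-", "CDS", 311, 328),
    feat("g2", "chr1", "-", "CDS", 339, 356),
    feat("g2", "chr1", "-", "five_prime_UTR", 357, 366))
  read_gene_models(rbind(g1, g2))
}

toy_ref <- function() {
  base <- strrep("A", 500)
  cds1 <- paste(g1_codons, collapse = "")
  # g1 plus strand: CDS bases 1-18 at 111-128, 19-36 at 139-156
  substr(base, 111, 128) <- substr(cds1, 1, 18)
  substr(base, 139, 156) <- substr(cds1, 19, 36)
  # g2 minus strand: coding order runs 356 -> 311 (high exon first)
  cds2 <- paste(g2_codons, collapse = "")
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # coding positions in genomic order 311..328 are the LAST 18 coding bases,
  # reverse complemented; 339..356 are the first 18
  substr(base, 339, 356) <- rc(substr(cds2, 1, 18))
  substr(base, 311, 328) <- rc(substr(cds2, 19, 36))
  c(chr1 = base)
}

# Single-codon gene fixture: CDS = one codon at 11-13 on the plus strand
one_codon_tx <- function(codon) {
  feat <- data.frame(
    type = c("gene", "mRNA", "exon", "CDS"),
    start = c(11L, 11L, 11L, 11L), end = c(13L, 13L, 13L, 13L),
    gene = "g", chrom = "chr1", strand = "+")
  models <- read_gene_models(feat)
  ref <- c(chr1 = paste0(strrep("A", 10), codon, strrep("A", 10)))
  list(tx = models$transcripts[[1]], ref = ref)
}

# Write a small VCF fixture file; returns its path
write_vcf_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.vcf")
  writeLines(lines, path)
  path
}
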