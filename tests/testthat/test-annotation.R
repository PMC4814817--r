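test_that("coding_effect agrees with direct codon-table translation on all 576 cases", {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (codon in names(code)) {
    fx <- one_codon_tx(codon)
    for (off in 1:3) {
      ref_base <- substr(codon, off, off)
      for (b in setdiff(bases, ref_base)) {
        alt_codon <- codon
        substr(alt_codon, off, off) <- b
        got <- coding_effect(fx$tx, 10L + off, ref_base, b, fx$ref)
        ref_aa <- code[[codon]]; alt_aa <- code[[alt_codon]]
        expect_identical(got$coding_effect,
                         if (ref_aa == alt_aa) "synonymous" else "nonsynonymous")
        expected_large <-
          if (alt_aa == "*" && ref_aa != "*") "premature_stop"
          else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
          else if (codon == "ATG" && alt_codon != "ATG") "start_loss"
          else "none"
        expect_identical(got$large_effect, expected_large)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_identical(n_checked, 576)
})

test_that("coding_effect validates the reference allele", {
  fx <- one_codon_tx("GGG")
  expect_error(coding_effect(fx$tx, 11L, "C", "T", fx$ref), "mismatch")
})

test_that("context classification follows the cds > utr > intron precedence", {
  models <- toy_models()
  ctx <- classify_context("chr1", c(50L, 105L, 115L, 132L, 160L, 320L, 360L),
                          models)
  expect_identical(ctx$context,
                   c("intergenic", "utr5", "cds", "intron", "utr3",
                     "cds", "utr5"))
})

test_that("overlapping transcripts are reported individually with a cds summary", {
  # g_a's intron overlaps g_b's CDS
  feat <- rbind(
    data.frame(type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS"),
               start = c(1L, 1L, 1L, 61L, 1L, 61L),
               end = c(90L, 90L, 30L, 90L, 30L, 90L),
               gene = "g_a", chrom = "chr1", strand = "+"),
    data.frame(type = c("gene", "mRNA", "exon", "CDS"),
               start = c(31L, 31L, 31L, 31L), end = c(57L, 57L, 57L, 57L),
               gene = "g_b", chrom = "chr1", strand = "+"))
  models <- read_gene_models(feat)
  ctx <- classify_context("chr1", 40L, models)
  expect_identical(ctx$context, "cds")
  expect_match(ctx$tx_calls, "g_a\\.t1:intron")
  expect_match(ctx$tx_calls, "g_b\\.t1:cds")
})

test_that("splice-site calls cover only the first/last window bases of introns", {
  models <- toy_models()
  tx <- models$transcripts[["g1.t1"]]
  # g1 intron spans 129-138
  expect_identical(splice_site_effect(tx, 129L), "splice_site") # donor G of GT
  expect_identical(splice_site_effect(tx, 130L), "splice_site")
  expect_identical(splice_site_effect(tx, 131L), "none")
  expect_identical(splice_site_effect(tx, 137L), "splice_site")
  expect_identical(splice_site_effect(tx, 120L), "none")        # exonic
  expect_identical(splice_site_effect(tx, 131L, window = 3L), "splice_site")
})

test_that("indels are classified by context and frame impact", {
  models <- toy_models()
  got <- classify_indel(rep("chr1", 4), c(115L, 120L, 132L, 50L),
                        c(-2L, -3L, 1L, 1L), models)
  expect_identical(got, c("cds_frameshift", "cds_inframe", "intron",
                          "intergenic"))
})

test_that("strand symmetry: minus-strand annotation equals its plus-strand mirror", {
  models <- toy_models()
  ref <- toy_ref()
  tx2 <- models$transcripts[["g2.t1"]]
  # codon 2 of g2 is CCA (Pro); its third base (coding base 6) sits at
  # genomic 351 (coding order runs 356 down to 339 for bases 1-18)
  pos <- 351L
  ref_base <- substr(ref[["chr1"]], pos, pos)
  # plus-strand G at this position is the complement of coding-strand C
  got <- coding_effect(tx2, pos, ref_base, "A", ref[["chr1"]])
  expect_identical(got$ref_codon, "CCA")
  # alt A on plus strand -> T in coding orientation: CCT, still Pro
  expect_identical(got$alt_codon, "CCT")
  expect_identical(got$coding_effect, "synonymous")
})

test_that("four-fold site extraction matches brute force on a toy gene", {
  # gene "ATG GCT GCC TAA": only the Ala codons' third positions qualify
  feat <- data.frame(type = c("gene", "mRNA", "exon", "CDS"),
                     start = 11L, end = 22L, gene = "g", chrom = "chr1",
                     strand = "+")
  models <- read_gene_models(feat)
  ref <- c(chr1 = paste0(strrep("A", 10), "ATGGCTGCCTAA", strrep("A", 10)))
  got <- four_fold_sites(models, ref)
  # brute force over every CDS position and all four substitutions
  code <- Biostrings::GENETIC_CODE
  cds <- "ATGGCTGCCTAA"
  expected <- integer(0)
  for (p in seq_len(nchar(cds))) {
    if (p %% 3 != 0) next
    codon <- substr(cds, p - 2, p)
    aas <- vapply(c("A", "C", "G", "T"), function(b) {
      cd <- codon; substr(cd, 3, 3) <- b; code[[cd]]
    }, "")
    if (length(unique(aas)) == 1) expected <- c(expected, 10L + p)
  }
  expect_identical(got$pos, expected)
  expect_identical(got$pos, c(16L, 19L))
})

test_that("a start+stop-only gene has no four-fold site", {
  feat <- data.frame(type = c("gene", "mRNA", "exon", "CDS"),
                     start = 11L, end = 16L, gene = "g", chrom = "chr1",
                     strand = "+")
  models <- read_gene_models(feat)
  ref <- c(chr1 = paste0(strrep("A", 10), "ATGTAA", strrep("A", 10)))
  expect_identical(nrow(four_fold_sites(models, ref)), 0L)
})

test_that("four-fold sites must be four-fold in every overlapping transcript", {
  # two plus-strand transcripts over the same bases, frames offset so a
  # position four-fold in t1 is internal (non-degenerate) in t2
  feat <- rbind(
    data.frame(type = c("gene", "mRNA", "exon", "CDS"),
               start = 11L, end = 22L, gene = "ga", chrom = "chr1",
               strand = "+"),
    data.frame(type = c("gene", "mRNA", "exon", "CDS"),
               start = 12L, end = 20L, gene = "gb", chrom = "chr1",
               strand = "+"))
  models <- read_gene_models(feat)
  # ga: ATG GGA CTT TAA -> GGA third pos (16) and CTT third pos (19)
  # are 4-fold in ga; in gb (frame starts at 12) both sites sit at codon
  # offset 2, so they are excluded by the every-transcript rule
  ref <- c(chr1 = paste0(strrep("A", 10), "ATGGGACTTTAA", strrep("A", 10)))
  got <- four_fold_sites(models, ref)
  solo <- read_gene_models(feat[feat$gene == "ga", ])
  got_solo <- four_fold_sites(solo, ref)
  expect_identical(got_solo$pos, c(16L, 19L))
  expect_identical(nrow(got), 0L)
})

test_that("frame-inconsistent transcripts are excluded with a warning", {
  feat <- data.frame(type = c("gene", "mRNA", "exon", "CDS"),
                     start = 11L, end = 21L, gene = "g", chrom = "chr1",
                     strand = "+")  # CDS length 11, not divisible by 3
  expect_warning(models <- read_gene_models(feat), "not divisible by 3")
  expect_false(models$transcripts[[1]]$coding_ok)
})

test_that("every SNP receives exactly one summary context class", {
  set.seed(8)
  models <- toy_models()
  ref <- toy_ref()
  pos <- sort(sample(setdiff(1:450, 0), 60))
  gm <- gm_fixture(matrix(sample(c(0L, 2L), 60 * 4, replace = TRUE), 60, 4),
                   pops = rep("wild", 4), pos = pos,
                   ref = substring(ref[["chr1"]], pos, pos),
                   alt = rep("T", 60))
  # avoid ref == alt
  gm$alt[gm$ref == "T"] <- "G"
  ann <- annotate_snps(gm, models, ref)
  expect_identical(nrow(ann), n_sites(gm))
  expect_true(all(ann$context %in% c("cds", "utr5", "utr3", "intron",
                                     "intergenic")))
  counts <- table(factor(ann$context, levels = c("cds", "utr5", "utr3",
                                                 "intron", "intergenic")))
  expect_identical(sum(counts), n_sites(gm))
})
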