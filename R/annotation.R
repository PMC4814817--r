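## Functional-effect annotation of SNPs and short indels against GFF3 gene
## models: genomic context, synonymous / non-synonymous calls, large-effect
## categories (premature stop, stop loss, start loss, splice site),
## frameshift indels and 4-fold degenerate site extraction.

CONTEXT_LEVELS <- c("cds", "utr5", "utr3", "intron", "intergenic")

#' Load gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon / CDS / UTR features (via
#' `rtracklayer::import`) into per-transcript structures with a
#' strand-aware CDS coordinate map.  Transcripts whose total CDS length
#' is not divisible by 3 are flagged and excluded from coding-effect
#' calls, with a warning.
#'
#' @param gff path to a GFF3 file, or a data frame as produced by
#'   [simulate_panel()] (columns type, start, end, gene, chrom, strand)
#' @return an object of class `gene_models`
#' @export
read_gene_models <- function(gff) {
  if (is.character(gff)) {
    gr <- rtracklayer::import(gff, format = "GFF3")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     type = as.character(gr$type),
                     id = if (is.null(gr$ID)) NA_character_ else gr$ID,
                     parent = vapply(as.list(gr$Parent %||%
                                               rep(list(character(0)), length(gr))),
                                     function(p) if (length(p)) p[[1]] else NA_character_,
                                     ""))
  } else {
    df <- as.data.frame(gff)
    ## the simulator's table identifies everything by gene id
    df$id <- ifelse(df$type == "gene", df$gene,
                    ifelse(df$type == "mRNA", paste0(df$gene, ".t1"), NA))
    df$parent <- ifelse(df$type == "gene", NA,
                        ifelse(df$type == "mRNA", df$gene, paste0(df$gene, ".t1")))
  }
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  tx <- list()
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$id[i]
    feats <- df[!is.na(df$parent) & df$parent == tid, ]
    cds <- feats[feats$type == "CDS", c("start", "end")]
    cds <- cds[order(cds$start), , drop = FALSE]
    strand <- mrna$strand[i]
    cds_len <- sum(cds$end - cds$start + 1L)
    coding_ok <- nrow(cds) > 0 && cds_len %% 3L == 0L
    if (nrow(cds) > 0 && !coding_ok)
      warning(sprintf("transcript %s: CDS length %d not divisible by 3; excluded from coding-effect calls",
                      tid, cds_len), call. = FALSE)
    ## genomic positions of the CDS in coding (5'->3') order
    cds_map <- integer(0)
    if (nrow(cds) > 0) {
      cds_map <- unlist(lapply(seq_len(nrow(cds)),
                               function(j) seq(cds$start[j], cds$end[j])))
      if (strand == "-") cds_map <- rev(cds_map)
    }
    exons <- feats[feats$type == "exon", c("start", "end")]
    exons <- exons[order(exons$start), , drop = FALSE]
    tx[[tid]] <- list(
      id = tid,
      gene = if (!is.na(mrna$parent[i])) mrna$parent[i] else tid,
      chrom = mrna$chrom[i], strand = strand,
      start = mrna$start[i], end = mrna$end[i],
      exons = exons,
      cds = cds, cds_map = cds_map, coding_ok = coding_ok,
      utr5 = feats[feats$type == "five_prime_UTR", c("start", "end")],
      utr3 = feats[feats$type == "three_prime_UTR", c("start", "end")])
  }
  genes <- df[df$type == "gene", c("id", "chrom", "start", "end", "strand")]
  names(genes)[1] <- "gene"
  rownames(genes) <- NULL
  structure(list(transcripts = tx, genes = genes), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s), %d transcript(s) on %d chromosome(s)\n",
              nrow(x$genes), length(x$transcripts),
              length(unique(x$genes$chrom))))
  invisible(x)
}

in_any <- function(pos, intervals) {
  ## intervals: data.frame(start, end), 1-based inclusive
  nrow(intervals) > 0 && any(pos >= intervals$start & pos <= intervals$end)
}

## Per-transcript context of a single position (transcript must span it)
tx_context <- function(tx, pos) {
  if (in_any(pos, tx$cds)) return("cds")
  if (in_any(pos, tx$utr5)) return("utr5")
  if (in_any(pos, tx$utr3)) return("utr3")
  "intron"
}

#' Classify the genomic context of sites
#'
#' For each site, every transcript spanning it contributes an
#' individual call (CDS, 5'/3' UTR or intron); the per-site summary
#' takes the highest-precedence class, `cds > utr5 > utr3 > intron >
#' intergenic`.
#'
#' @param chrom,pos site coordinates (1-based), vectors of equal length
#' @param models a [read_gene_models()] object
#' @return data frame with `chrom`, `pos`, summary `context`, and
#'   `tx_calls` (comma-separated `transcript:context` for every
#'   overlapping transcript)
#' @export
classify_context <- function(chrom, pos, models) {
  chrom <- rep_len(chrom, length(pos))
  tx <- models$transcripts
  tx_chrom <- vapply(tx, `[[`, "", "chrom")
  tx_start <- vapply(tx, `[[`, 0, "start")
  tx_end <- vapply(tx, `[[`, 0, "end")
  context <- character(length(pos))
  tx_calls <- character(length(pos))
  for (i in seq_along(pos)) {
    hit <- which(tx_chrom == chrom[i] & tx_start <= pos[i] & tx_end >= pos[i])
    if (!length(hit)) {
      context[i] <- "intergenic"
      tx_calls[i] <- ""
      next
    }
    calls <- vapply(tx[hit], tx_context, "", pos = pos[i])
    context[i] <- CONTEXT_LEVELS[min(match(calls, CONTEXT_LEVELS))]
    tx_calls[i] <- paste(names(tx)[hit], calls, sep = ":", collapse = ",")
  }
  data.frame(chrom = chrom, pos = pos, context = context,
             tx_calls = tx_calls)
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

## Codon containing CDS-coordinate i (1-based within the coding sequence)
## of transcript tx, read off the reference; returns list(codon, offset)
tx_codon <- function(tx, cds_i, ref_seq) {
  codon_idx <- (cds_i - 1L) %/% 3L
  offs <- codon_idx * 3L + 1:3
  gpos <- tx$cds_map[offs]
  bases <- substring(ref_seq, gpos, gpos)
  if (tx$strand == "-") bases <- comp_base(bases)
  list(codon = paste(bases, collapse = ""), offset = cds_i - codon_idx * 3L,
       codon_idx = codon_idx + 1L)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Coding consequence of a SNP within one transcript
#'
#' Translates the reference and alternate codons (reverse-complemented
#' for minus-strand transcripts) with the standard nuclear codon table.
#' Same amino acid: synonymous; different: non-synonymous.  Large-effect
#' categories: alternate codon is a stop while the reference is not
#' (premature stop), reference codon is a stop while the alternate is
#' not (stop loss), or the site lies in the annotated initiator ATG and
#' the alternate codon is no longer ATG (start loss).
#'
#' @param tx one transcript entry of a `gene_models` object
#' @param pos genomic position (1-based) inside the transcript's CDS
#' @param ref,alt SNP alleles on the plus strand of the reference
#' @param ref_seq reference chromosome sequence as a character string
#' @return list with `coding_effect` (`synonymous` / `nonsynonymous`)
#'   and `large_effect` (`premature_stop`, `stop_loss`, `start_loss` or
#'   `none`)
#' @export
coding_effect <- function(tx, pos, ref, alt, ref_seq) {
  if (!tx$coding_ok) abort("transcript %s is frame-inconsistent", tx$id)
  cds_i <- match(pos, tx$cds_map)
  if (is.na(cds_i)) abort("position %d is not in the CDS of %s", pos, tx$id)
  if (substring(ref_seq, pos, pos) != ref)
    abort("reference allele mismatch at %s:%d", tx$chrom, pos)
  cz <- tx_codon(tx, cds_i, ref_seq)
  ref_codon <- cz$codon
  sub_base <- if (tx$strand == "-") comp_base(alt) else alt
  alt_codon <- ref_codon
  substr(alt_codon, cz$offset, cz$offset) <- sub_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- if (identical(ref_aa, alt_aa)) "synonymous" else "nonsynonymous"
  large <- "none"
  if (alt_aa == "*" && ref_aa != "*") large <- "premature_stop"
  else if (ref_aa == "*" && alt_aa != "*") large <- "stop_loss"
  else if (cz$codon_idx == 1L && ref_codon == "ATG" && alt_codon != "ATG")
    large <- "start_loss"
  list(coding_effect = effect, large_effect = large,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa)
}

## Intron intervals of a transcript (gaps between consecutive exons)
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Splice-site test for an intronic SNP
#'
#' A SNP is a splice-site variant when it falls within the first or
#' last `window` bases of any intron of a spanning transcript (the
#' canonical GT/AG donor/acceptor dinucleotides at `window = 2`).
#'
#' @param tx one transcript entry of a `gene_models` object
#' @param pos genomic position (1-based)
#' @param window bases at each intron end considered splice-critical
#' @return `"splice_site"` or `"none"`
#' @export
splice_site_effect <- function(tx, pos, window = 2L) {
  intr <- tx_introns(tx)
  for (i in seq_len(nrow(intr))) {
    if (pos >= intr$start[i] && pos <= intr$end[i]) {
      if (pos < intr$start[i] + window || pos > intr$end[i] - window)
        return("splice_site")
    }
  }
  "none"
}

#' Classify short indels by context and reading-frame impact
#'
#' CDS indels whose net length change is not a multiple of 3 are
#' frameshifts; multiples of 3 are in-frame.  Outside the CDS the call
#' is the context class (5' and 3' UTR collapsed to `utr`).
#'
#' @param chrom,pos,dlen indel coordinates and net length changes
#' @param models a [read_gene_models()] object
#' @return character vector over `{intergenic, intron, utr,
#'   cds_inframe, cds_frameshift}`
#' @export
classify_indel <- function(chrom, pos, dlen, models) {
  ctx <- classify_context(chrom, pos, models)$context
  out <- ctx
  out[ctx %in% c("utr5", "utr3")] <- "utr"
  in_cds <- ctx == "cds"
  out[in_cds & (abs(dlen) %% 3L != 0L)] <- "cds_frameshift"
  out[in_cds & (abs(dlen) %% 3L == 0L)] <- "cds_inframe"
  out
}

## All third-codon-position CDS coordinates of tx that are 4-fold
## degenerate, as genomic positions
tx_four_fold <- function(tx, ref_seq) {
  if (!tx$coding_ok || length(tx$cds_map) == 0) return(integer(0))
  n_codon <- length(tx$cds_map) %/% 3L
  out <- integer(0)
  for (ci in seq_len(n_codon)) {
    gpos <- tx$cds_map[(ci - 1L) * 3L + 1:3]
    bases <- substring(ref_seq, gpos, gpos)
    if (tx$strand == "-") bases <- comp_base(bases)
    codon <- paste(bases, collapse = "")
    aas <- vapply(c("A", "C", "G", "T"), function(b) {
      cd <- codon
      substr(cd, 3, 3) <- b
      translate_codon(cd)
    }, "")
    if (length(unique(aas)) == 1L) out <- c(out, gpos[3L])
  }
  out
}

#' Extract 4-fold degenerate genomic positions
#'
#' Third codon positions whose amino acid is invariant to all four
#' nucleotides, computed per transcript on the coding strand and mapped
#' back to genomic coordinates.  A position is retained only if it is
#' 4-fold degenerate in every transcript whose CDS covers it, so the
#' returned set is safe to use as a quasi-neutral marker panel.
#'
#' @param models a [read_gene_models()] object
#' @param ref named character vector (or `DNAStringSet`) of chromosome
#'   sequences
#' @return data frame with `chrom` and `pos` (sorted)
#' @export
four_fold_sites <- function(models, ref) {
  ref <- as_ref_strings(ref)
  per_chrom <- list()
  for (tx in models$transcripts) {
    rs <- ref[[tx$chrom]]
    if (is.null(rs)) abort("no reference sequence for %s", tx$chrom)
    ff <- tx_four_fold(tx, rs)
    cds_all <- if (length(tx$cds_map)) tx$cds_map else integer(0)
    entry <- per_chrom[[tx$chrom]] %||% list(ff = integer(0), not_ff = integer(0))
    entry$ff <- c(entry$ff, ff)
    entry$not_ff <- c(entry$not_ff, setdiff(cds_all, ff))
    per_chrom[[tx$chrom]] <- entry
  }
  out <- lapply(names(per_chrom), function(ch) {
    e <- per_chrom[[ch]]
    keep <- setdiff(unique(e$ff), unique(e$not_ff))
    if (length(keep)) data.frame(chrom = ch, pos = sort(keep)) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(0), pos = integer(0)) else out
}

as_ref_strings <- function(ref) {
  if (methods::is(ref, "DNAStringSet")) {
    stats::setNames(as.character(ref), names(ref))
  } else {
    ref
  }
}

#' Annotate every SNP of a genotype matrix
#'
#' One-stop wrapper: genomic context, coding effect (per the
#' highest-precedence spanning transcript with a frame-consistent CDS),
#' and large-effect category including intronic splice-site calls.
#'
#' @param gm a [genotype_matrix()]
#' @param models a [read_gene_models()] object
#' @param ref reference sequences (named character or `DNAStringSet`)
#' @param splice_window splice-site window in bp (default 2)
#' @return data frame with one row per site: `chrom`, `pos`, `context`,
#'   `gene`, `coding_effect`, `large_effect`
#' @export
annotate_snps <- function(gm, models, ref, splice_window = 2L) {
  ref <- as_ref_strings(ref)
  ctx <- classify_context(gm$chrom, gm$pos, models)
  n <- n_sites(gm)
  eff <- rep("none", n)
  large <- rep("none", n)
  gene <- rep(NA_character_, n)
  tx <- models$transcripts
  for (i in seq_len(n)) {
    if (ctx$tx_calls[i] == "") next
    calls <- strsplit(strsplit(ctx$tx_calls[i], ",")[[1]], ":")
    tids <- vapply(calls, `[[`, "", 1L)
    ccls <- vapply(calls, `[[`, "", 2L)
    gene[i] <- tx[[tids[1]]]$gene
    if (ctx$context[i] == "cds") {
      cand <- tids[ccls == "cds"]
      cand <- cand[vapply(cand, function(t) tx[[t]]$coding_ok, TRUE)]
      if (length(cand)) {
        ce <- coding_effect(tx[[cand[1]]], gm$pos[i], gm$ref[i], gm$alt[i],
                            ref[[gm$chrom[i]]])
        eff[i] <- ce$coding_effect
        large[i] <- ce$large_effect
        gene[i] <- tx[[cand[1]]]$gene
      }
    } else if (ctx$context[i] == "intron") {
      for (t in tids[ccls == "intron"]) {
        if (splice_site_effect(tx[[t]], gm$pos[i], splice_window) == "splice_site") {
          large[i] <- "splice_site"
          gene[i] <- tx[[t]]$gene
          break
        }
      }
    }
  }
  data.frame(chrom = gm$chrom, pos = gm$pos, context = ctx$context,
             gene = gene, coding_effect = eff, large_effect = large)
}
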