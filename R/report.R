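## Group-wise summary tables, shared/private SNP accounting and the
## derived ratios and percentages of the pipeline report.

## Is each site polymorphic within the given sample subset?
polymorphic_in <- function(gm, samples) {
  g <- gm$geno[, samples, drop = FALSE]
  n_ref <- rowSums(g == 0L, na.rm = TRUE) * 2L + rowSums(g == 1L, na.rm = TRUE)
  n_alt <- rowSums(g == 2L, na.rm = TRUE) * 2L + rowSums(g == 1L, na.rm = TRUE)
  n_ref > 0 & n_alt > 0
}

#' Group-wise SNP summary (Table-1 style)
#'
#' A site counts for a group when it is polymorphic within that group's
#' samples.  Context counts use the per-site summary context; the exon
#' column is the CDS + UTR total as in genic summaries.  The
#' non-synonymous / synonymous ratio is rounded half-up to 2 decimals;
#' a group with no synonymous SNPs gets the `NA` sentinel.
#'
#' @param gm a [genotype_matrix()]
#' @param annotations data frame from [annotate_snps()] covering every
#'   site of `gm`
#' @param groups named list of population-label vectors (default: one
#'   group per label present)
#' @return data frame with one row per group: total, context counts,
#'   synonymous / nonsynonymous counts and their ratio
#' @export
summarize_groups <- function(gm, annotations, groups = NULL) {
  if (n_sites(gm) != nrow(annotations))
    abort("summarize_groups(): annotations must cover every site")
  if (is.null(groups)) {
    labs <- unique(gm$pops)
    groups <- stats::setNames(as.list(labs), labs)
  }
  rows <- list()
  for (g in names(groups)) {
    samp <- samples_of(gm, groups[[g]])
    if (!length(samp)) abort("summarize_groups(): group '%s' is empty", g)
    poly <- polymorphic_in(gm, samp)
    ann <- annotations[poly, ]
    n_syn <- sum(ann$coding_effect == "synonymous")
    n_non <- sum(ann$coding_effect == "nonsynonymous")
    rows[[g]] <- data.frame(
      group = g, total = sum(poly),
      intergenic = sum(ann$context == "intergenic"),
      intron = sum(ann$context == "intron"),
      utr5 = sum(ann$context == "utr5"),
      utr3 = sum(ann$context == "utr3"),
      cds = sum(ann$context == "cds"),
      synonymous = n_syn, nonsynonymous = n_non,
      nonsyn_syn_ratio = if (n_syn > 0) round_half_up(n_non / n_syn, 2)
                         else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shared and private SNP accounting across groups
#'
#' Membership is polymorphism within a group; every site of the union
#' is assigned to exactly one group subset (the set of groups in which
#' it segregates), so subset counts sum to the union total.
#'
#' @param gm a [genotype_matrix()]
#' @param groups named list of population-label vectors (default: one
#'   group per label present)
#' @return list with `subsets` (data frame: subset label, count),
#'   `totals` (per-group polymorphic counts), and `pairwise` (data
#'   frame: for each ordered pair, shared count and percentage of the
#'   first group's total)
#' @export
shared_private <- function(gm, groups = NULL) {
  if (is.null(groups)) {
    labs <- unique(gm$pops)
    groups <- stats::setNames(as.list(labs), labs)
  }
  if (length(groups) < 2) abort("shared_private(): need >= 2 groups")
  memb <- vapply(names(groups),
                 function(g) polymorphic_in(gm, samples_of(gm, groups[[g]])),
                 logical(n_sites(gm)))
  if (n_sites(gm) == 1) memb <- matrix(memb, nrow = 1,
                                       dimnames = list(NULL, names(groups)))
  in_union <- rowSums(memb) > 0
  key <- apply(memb[in_union, , drop = FALSE], 1,
               function(r) paste(names(groups)[r], collapse = "+"))
  subsets <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(subsets) <- c("subset", "count")
  totals <- colSums(memb)
  gn <- names(groups)
  pw <- list()
  for (a in gn) for (b in setdiff(gn, a)) {
    shared <- sum(memb[, a] & memb[, b])
    pw[[length(pw) + 1L]] <- data.frame(
      group = a, with = b, shared = shared,
      pct_of_group = if (totals[[a]] > 0) percent_of(shared, totals[[a]], 0)
                     else NA_real_)
  }
  list(subsets = subsets, totals = totals,
       pairwise = do.call(rbind, pw), n_union = sum(in_union))
}

#' Large-effect SNP counts by category
#'
#' Site-level counts of the four large-effect categories plus the
#' unique gene count carrying at least one such SNP.
#'
#' @param annotations data frame from [annotate_snps()]
#' @return list with `by_category` (named counts), `total` (their sum)
#'   and `n_genes`
#' @export
large_effect_summary <- function(annotations) {
  cats <- c("premature_stop", "stop_loss", "start_loss", "splice_site")
  by_cat <- vapply(cats, function(c) sum(annotations$large_effect == c), 0L)
  hit <- annotations$large_effect %in% cats
  list(by_category = by_cat, total = sum(by_cat),
       n_genes = length(unique(annotations$gene[hit & !is.na(annotations$gene)])))
}
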