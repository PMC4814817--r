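## The pi-ratio selective-sweep scan: window diversity ratios between a
## diverse and a selected group, a minimum-diversity filter, top-quantile
## window selection, locus merging and gene overlap.

#' Window diversity ratios between two groups
#'
#' One ratio per window with defined diversity in both groups:
#' `pi_diverse / pi_selected`, with `Inf` when the selected group's
#' diversity is zero while the diverse group's is positive.  Windows
#' with an undefined (sentinel) diversity in either group are dropped
#' with a message.
#'
#' @param stats window-statistics data frame from [window_stats()]
#' @param diverse,selected group names; `pi_<name>` columns must exist
#' @return data frame `chrom`, `start`, `end`, `pi_div`, `pi_sel`,
#'   `ratio`, sorted by (chrom, start)
#' @export
compute_ratios <- function(stats, diverse, selected) {
  cd <- paste0("pi_", diverse); cs <- paste0("pi_", selected)
  if (!cd %in% names(stats)) abort("unknown group '%s' (no column %s)", diverse, cd)
  if (!cs %in% names(stats)) abort("unknown group '%s' (no column %s)", selected, cs)
  pi_div <- stats[[cd]]; pi_sel <- stats[[cs]]
  ok <- !is.na(pi_div) & !is.na(pi_sel)
  if (any(!ok))
    message(sprintf("compute_ratios: dropped %d window(s) with undefined pi", sum(!ok)))
  out <- data.frame(chrom = stats$chrom[ok], start = stats$start[ok],
                    end = stats$end[ok], pi_div = pi_div[ok],
                    pi_sel = pi_sel[ok])
  out$ratio <- ifelse(out$pi_sel > 0, out$pi_div / out$pi_sel,
                      ifelse(out$pi_div > 0, Inf, NA_real_))
  out <- out[!is.na(out$ratio), ]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Select candidate sweep windows
#'
#' Drops windows whose diverse-group diversity is below `min_pi`, ranks
#' the remainder by ratio (`Inf` first, among them by higher diverse-
#' group diversity, then by coordinate) and keeps the top `top_frac`
#' fraction (`ceiling(top_frac * n)` windows); windows tied with the
#' cutoff ratio are all kept.
#'
#' @param ratios data frame from [compute_ratios()]
#' @param min_pi minimum diverse-group diversity (default 0.002)
#' @param top_frac quantile fraction kept (default 0.05)
#' @return the selected subset of `ratios`, sorted by (chrom, start)
#' @export
select_windows <- function(ratios, min_pi = 0.002, top_frac = 0.05) {
  if (nrow(ratios) == 0) abort("select_windows(): no ratio windows")
  retained <- ratios[ratios$pi_div >= min_pi, ]
  if (nrow(retained) == 0) {
    warning("select_windows(): every window fell below the minimum diversity filter",
            call. = FALSE)
    return(retained)
  }
  ord <- order(-retained$ratio, -retained$pi_div,
               retained$chrom, retained$start)
  retained <- retained[ord, ]
  n_keep <- ceiling(top_frac * nrow(retained))
  cutoff <- retained$ratio[n_keep]
  sel <- retained[seq_len(nrow(retained)) <= n_keep | retained$ratio == cutoff, ]
  sel <- sel[order(sel$chrom, sel$start), ]
  rownames(sel) <- NULL
  sel
}

#' Merge selected windows into sweep loci
#'
#' Consecutive selected windows that overlap, or whose end-to-start gap
#' is at most `max_gap` bp, join one locus.  The locus spans the
#' minimum start to the maximum end; its peak ratio is the largest
#' member ratio.
#'
#' @param selected data frame from [select_windows()]
#' @param max_gap largest merged gap in bp (default 50 kb)
#' @return data frame of loci: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_ratio`, `span`
#' @export
merge_loci <- function(selected, max_gap = 50000L) {
  if (nrow(selected) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      peak_ratio = numeric(0), span = numeric(0)))
  sel <- selected[order(selected$chrom, selected$start), ]
  loci <- list()
  cur <- sel[1, ]
  cur_n <- 1L
  cur_peak <- sel$ratio[1]
  flush <- function() {
    loci[[length(loci) + 1L]] <<- data.frame(
      chrom = cur$chrom, start = cur$start, end = cur$end,
      n_windows = cur_n, peak_ratio = cur_peak, span = cur$end - cur$start)
  }
  for (i in seq_len(nrow(sel))[-1]) {
    same <- sel$chrom[i] == cur$chrom
    gap <- sel$start[i] - cur$end
    if (same && gap <= max_gap) {
      cur$end <- max(cur$end, sel$end[i])
      cur_n <- cur_n + 1L
      cur_peak <- max(cur_peak, sel$ratio[i])
    } else {
      flush()
      cur <- sel[i, ]; cur_n <- 1L; cur_peak <- sel$ratio[i]
    }
  }
  flush()
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Attach overlapping genes and scan totals to sweep loci
#'
#' A gene overlaps a locus when their spans intersect by at least 1 bp.
#'
#' @param loci data frame from [merge_loci()]
#' @param models a [read_gene_models()] object, or `NULL`
#' @param genome_size optional denominator (bp) for the span percentage
#' @return list with `loci` (plus a `genes` list-column and `n_genes`)
#'   and `summary` (locus count, total span, unique gene count, span
#'   percentage when `genome_size` is given)
#' @export
annotate_loci <- function(loci, models = NULL, genome_size = NULL) {
  gene_lists <- vector("list", nrow(loci))
  if (!is.null(models) && nrow(loci)) {
    gt <- models$genes  # 1-based inclusive spans
    for (i in seq_len(nrow(loci))) {
      ## locus is 0-based half-open: genomic bases loci$start+1 .. loci$end
      hit <- gt$chrom == loci$chrom[i] &
        gt$start <= loci$end[i] & gt$end >= loci$start[i] + 1
      gene_lists[[i]] <- gt$gene[hit]
    }
  }
  loci$n_genes <- lengths(gene_lists)
  loci$genes <- I(gene_lists)
  all_genes <- unique(unlist(gene_lists))
  summary <- list(n_loci = nrow(loci),
                  total_span = sum(loci$span %||% (loci$end - loci$start)),
                  n_genes = length(all_genes))
  if (!is.null(genome_size))
    summary$span_pct <- percent_of(summary$total_span, genome_size, 1)
  list(loci = loci, summary = summary)
}

#' Run the full diversity-ratio sweep scan
#'
#' Chains [compute_ratios()], [select_windows()], [merge_loci()] and
#' [annotate_loci()]: the domestication-style scan contrasts a diverse
#' group (e.g. wild) against a selected group (e.g. the pooled
#' cultivated landrace+elite gene pool); the artificial-selection scan
#' applies the identical procedure to landrace (diverse) versus elite
#' (selected).
#'
#' @param stats window statistics from [window_stats()]
#' @param diverse,selected group names present in `stats`
#' @param min_pi,top_frac,merge_gap scan parameters (defaults: 0.002,
#'   0.05, 50 kb)
#' @param models optional [read_gene_models()] for gene overlap
#' @param genome_size optional genome length for the span percentage
#' @return object of class `sweep_scan` with elements `ratios`,
#'   `selected`, `loci`, `summary` and the parameters used
#' @export
sweep_scan <- function(stats, diverse, selected, min_pi = 0.002,
                       top_frac = 0.05, merge_gap = 50000L,
                       models = NULL, genome_size = NULL) {
  ratios <- compute_ratios(stats, diverse, selected)
  sel <- select_windows(ratios, min_pi = min_pi, top_frac = top_frac)
  loci <- merge_loci(sel, max_gap = merge_gap)
  ann <- annotate_loci(loci, models, genome_size)
  structure(list(ratios = ratios, selected = sel, loci = ann$loci,
                 summary = ann$summary,
                 params = list(diverse = diverse, selected = selected,
                               min_pi = min_pi, top_frac = top_frac,
                               merge_gap = merge_gap)),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  p <- x$params
  cat(sprintf("sweep_scan: %s (diverse) vs %s (selected)\n", p$diverse, p$selected))
  cat(sprintf("  %d ratio windows; %d selected (pi >= %g, top %g%%)\n",
              nrow(x$ratios), nrow(x$selected), p$min_pi, 100 * p$top_frac))
  cat(sprintf("  %d locus/loci spanning %g bp", x$summary$n_loci,
              x$summary$total_span))
  if (!is.null(x$summary$span_pct))
    cat(sprintf(" (%.1f%% of the genome)", x$summary$span_pct))
  cat(sprintf(", %d gene(s)\n", x$summary$n_genes))
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  loci <- object$loci
  loci$genes <- NULL
  print(object)
  if (nrow(loci)) {
    cat("\nLoci:\n")
    print(loci, row.names = FALSE)
  }
  invisible(loci)
}

#' Write sweep loci as a BED file (0-based half-open)
#'
#' @param scan a `sweep_scan` object (or a loci data frame)
#' @param path output path
#' @return the path, invisibly
#' @export
write_loci_bed <- function(scan, path) {
  loci <- if (inherits(scan, "sweep_scan")) scan$loci else scan
  lines <- sprintf("%s\t%d\t%d\tlocus_%d\t%s", loci$chrom,
                   as.integer(loci$start), as.integer(loci$end),
                   seq_len(nrow(loci)),
                   ifelse(is.finite(loci$peak_ratio),
                          formatC(loci$peak_ratio, format = "g"), "inf"))
  writeLines(lines, path)
  invisible(path)
}
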