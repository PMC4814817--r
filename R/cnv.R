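## Depth-based CNV segmentation: flag bins at < 0.5x / > 2.0x of the
## sample's mean depth, join flagged runs in a permissive pass, retain
## strict segments of > 2 kb.

#' Read per-sample depth tracks
#'
#' TSV with header columns sample, chrom, start, end, depth (0-based
#' half-open bins).
#'
#' @param path file path
#' @return data frame
#' @export
read_depth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(sample = "character", chrom = "character"))
}

## Two-pass run merge on one chromosome's flagged bins of one type.
## runs: data.frame(first, last) of bin indices; flagged: logical per bin.
merge_runs <- function(runs, flagged, p_initial) {
  repeat {
    if (nrow(runs) < 2) return(runs)
    merged <- FALSE
    i <- 1L
    while (i < nrow(runs)) {
      span <- runs$first[i]:runs$last[i + 1]
      if (mean(flagged[span]) >= p_initial) {
        runs$last[i] <- runs$last[i + 1]
        runs <- runs[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) return(runs)
  }
}

#' Call copy-number variants from one sample's depth track
#'
#' Bins with mean depth strictly below half, or strictly above double,
#' the sample's genome-wide mean are flagged as loss / gain candidates.
#' An initial permissive pass joins same-type flagged runs across gaps
#' while the flagged-bin fraction of the joined span stays at or above
#' `merge_p_initial`; a final strict pass retains joined segments whose
#' flagged fraction is at least `merge_p_final` and whose length
#' exceeds `min_len` bp.  The reported fold is the segment's mean depth
#' over the sample mean.
#'
#' @param track data frame with columns chrom, start, end, depth (one
#'   sample; 0-based half-open bins), optionally a `sample` column
#' @param merge_p_initial,merge_p_final flagged-fraction thresholds of
#'   the permissive and strict passes (defaults 0.5 and 0.8)
#' @param min_len minimum segment length in bp (default 2000; segments
#'   must be strictly longer)
#' @param per_chrom normalise by per-chromosome rather than genome-wide
#'   mean depth (default `FALSE`)
#' @return data frame of segments: sample, chrom, start, end, type
#'   (`loss`/`gain`), fold, n_bins
#' @export
call_cnv <- function(track, merge_p_initial = 0.5, merge_p_final = 0.8,
                     min_len = 2000L, per_chrom = FALSE) {
  sample_id <- if (!is.null(track$sample)) track$sample[1] else NA_character_
  gmean <- mean(track$depth)
  if (!is.finite(gmean) || gmean <= 0)
    abort("call_cnv(): sample mean depth must be > 0")
  segs <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    tr <- tr[order(tr$start), ]
    m <- if (per_chrom) mean(tr$depth) else gmean
    if (!is.finite(m) || m <= 0) next
    for (type in c("loss", "gain")) {
      flagged <- if (type == "loss") tr$depth < 0.5 * m else tr$depth > 2.0 * m
      if (!any(flagged)) next
      r <- rle(flagged)
      last <- cumsum(r$lengths)
      first <- last - r$lengths + 1L
      runs <- data.frame(first = first[r$values], last = last[r$values])
      runs <- merge_runs(runs, flagged, merge_p_initial)
      for (i in seq_len(nrow(runs))) {
        span <- runs$first[i]:runs$last[i]
        seg_start <- tr$start[runs$first[i]]
        seg_end <- tr$end[runs$last[i]]
        if (mean(flagged[span]) >= merge_p_final &&
            seg_end - seg_start > min_len) {
          segs[[length(segs) + 1L]] <- data.frame(
            sample = sample_id, chrom = ch,
            start = seg_start, end = seg_end, type = type,
            fold = mean(tr$depth[span]) / m, n_bins = length(span))
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      type = character(0), fold = numeric(0),
                      n_bins = integer(0)))
  out <- do.call(rbind, segs)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Call CNVs for every sample of a multi-sample depth table
#'
#' @param depth data frame as from [read_depth()] (column `sample`
#'   distinguishes tracks)
#' @param ... passed to [call_cnv()]
#' @return combined segment data frame
#' @export
call_cnv_all <- function(depth, ...) {
  out <- lapply(split(depth, depth$sample), call_cnv, ...)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-gene copy-state table by group
#'
#' For each gene and sample the copy state is `loss`, `gain` or
#' `normal` according to the sample's segment with the largest overlap
#' of the gene span; per-group counts of each state are tabulated.
#'
#' @param segments segment data frame from [call_cnv_all()]
#' @param groups named character vector: group label per sample (all
#'   samples that were segmented, including those without calls)
#' @param models a [read_gene_models()] object
#' @return data frame with one row per gene x group: gene, group,
#'   n_loss, n_normal, n_gain
#' @export
cnv_group_compare <- function(segments, groups, models) {
  samples <- names(groups)
  if (length(samples) < 2) abort("cnv_group_compare(): need >= 2 samples")
  gt <- models$genes
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    ## gene span 1-based inclusive -> 0-based half-open
    gs <- gt$start[i] - 1L; ge <- gt$end[i]
    state <- stats::setNames(rep("normal", length(samples)), samples)
    for (s in samples) {
      seg <- segments[segments$sample == s & segments$chrom == gt$chrom[i], ]
      if (!nrow(seg)) next
      ov <- pmin(seg$end, ge) - pmax(seg$start, gs)
      if (any(ov > 0)) state[s] <- seg$type[which.max(ov)]
    }
    for (g in unique(groups)) {
      st <- state[groups == g]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gt$gene[i], group = g,
        n_loss = sum(st == "loss"), n_normal = sum(st == "normal"),
        n_gain = sum(st == "gain"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
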