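## Sliding-window diversity statistics (theta-pi, Watterson's theta-w,
## Tajima's D), Hudson Fst, LD r^2 decay and haplotype-identity grouping.
##
## All estimators operate on the inbred haplotype encoding (one haplotype
## per line, residual heterozygotes treated as missing; see haplotypes()).

## Per-site allele counts from a haplotype matrix (sites x haps, 0/1/NA)
site_counts <- function(h) {
  n1 <- rowSums(h == 1L, na.rm = TRUE)
  n0 <- rowSums(h == 0L, na.rm = TRUE)
  list(n0 = n0, n1 = n1, ns = n0 + n1)
}

#' Nucleotide diversity (theta-pi) of a window
#'
#' Mean pairwise difference per site: at each segregating site the
#' number of pairwise differences among the observed haplotypes
#' (pairwise deletion of missing data), summed over sites and divided
#' by the window length in bp.
#'
#' @param h haplotype matrix (sites x haplotypes, 0/1/NA); rows are the
#'   window's segregating sites, monomorphic positions need not appear
#' @param L window length in bp
#' @return per-site pi; `NA` when no site has two observed haplotypes
#' @export
theta_pi <- function(h, L) {
  if (L < 1) abort("theta_pi(): L must be >= 1")
  if (nrow(h) == 0) return(0)
  sc <- site_counts(h)
  usable <- sc$ns >= 2
  if (!any(usable)) return(NA_real_)
  contrib <- 2 * sc$n0[usable] * sc$n1[usable] /
    (sc$ns[usable] * (sc$ns[usable] - 1))
  sum(contrib) / L
}

#' Watterson's estimator (theta-w) per site
#'
#' `S / (a * L)` with `a` the harmonic number over `n - 1`.
#'
#' @param S number of segregating sites
#' @param n number of haplotypes
#' @param L window length in bp
#' @return per-site theta-w
#' @export
theta_w <- function(S, n, L) {
  if (!is_count(n) || n < 2) abort("theta_w(): n must be >= 2")
  if (L < 1) abort("theta_w(): L must be >= 1")
  S / (harmonic(n - 1) * L)
}

## Tajima (1989) normalising constants for sample size n
tajima_constants <- function(n) {
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of a window
#'
#' Standard normalized difference between the mean pairwise difference
#' and the segregating-site estimate of theta.  Returns the undefined
#' sentinel (`NA`) when the window has no segregating site.
#'
#' @param h haplotype matrix (sites x haplotypes, 0/1/NA)
#' @return Tajima's D, or `NA` when `S = 0`
#' @export
tajimas_d <- function(h) {
  n <- ncol(h)
  if (n < 2) abort("tajimas_d(): need >= 2 haplotypes")
  sc <- site_counts(h)
  seg <- sc$n0 > 0 & sc$n1 > 0
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  ## at n = 2 the numerator is identically zero (kbar = S = S/a1) and the
  ## normalising constants vanish; the statistic is defined as 0 there
  if (n == 2) return(0)
  usable <- sc$ns >= 2
  kbar <- sum(2 * sc$n0[usable] * sc$n1[usable] /
                (sc$ns[usable] * (sc$ns[usable] - 1)))
  k <- tajima_constants(n)
  (kbar - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Hudson's Fst between two windows of haplotypes
#'
#' Ratio-of-averages estimator: `1 - mean(Hw) / mean(Hb)` across sites,
#' with unbiased within-population heterozygosity
#' `n/(n-1) * 2*p*(1-p)` averaged over the two populations, and
#' between-population heterozygosity `p1*(1-p2) + p2*(1-p1)`.  Sites
#' need at least two observed haplotypes in each population.
#'
#' @param h1,h2 haplotype matrices over the same sites (rows)
#' @return Fst, or `NA` when the mean between-population
#'   heterozygosity is zero (both populations monomorphic and identical)
#' @export
hudson_fst <- function(h1, h2) {
  if (nrow(h1) != nrow(h2)) abort("hudson_fst(): site sets differ")
  if (ncol(h1) < 2 || ncol(h2) < 2) abort("hudson_fst(): need >= 2 haplotypes per population")
  s1 <- site_counts(h1); s2 <- site_counts(h2)
  ok <- s1$ns >= 2 & s2$ns >= 2
  if (!any(ok)) return(NA_real_)
  p1 <- s1$n1[ok] / s1$ns[ok]; p2 <- s2$n1[ok] / s2$ns[ok]
  n1 <- s1$ns[ok]; n2 <- s2$ns[ok]
  hw <- (n1 / (n1 - 1) * 2 * p1 * (1 - p1) +
           n2 / (n2 - 1) * 2 * p2 * (1 - p2)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(hb) == 0) return(NA_real_)
  1 - sum(hw) / sum(hb)
}

#' Sliding-window diversity and differentiation statistics
#'
#' Tiles each chromosome with windows of `window` bp every `step` bp,
#' anchored at coordinate 0, trailing partial window included, and
#' computes per group: segregating sites `S`, per-site theta-pi and
#' theta-w, Tajima's D; and per group pair: Hudson's Fst.  Windows with
#' no genotyped site carry `NA` sentinels (not zeros) so downstream
#' ratio scans can distinguish "no data" from "no diversity".
#'
#' @param gm a [genotype_matrix()]
#' @param groups named list of population-label vectors, e.g.
#'   `list(wild = "wild", cultivated = c("landrace", "elite"))`;
#'   default one group per population label present
#' @param window,step window length and step in bp
#' @param chrom_len named vector of chromosome lengths; defaults to the
#'   largest observed position per chromosome
#' @param fst compute pairwise Fst columns (default `TRUE`)
#' @return data frame with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open) and per-group / per-pair statistic columns
#' @export
window_stats <- function(gm, groups = NULL, window = 50000L, step = 5000L,
                         chrom_len = NULL, fst = TRUE) {
  if (step > window) abort("window_stats(): step must be <= window")
  if (is.null(groups)) {
    labs <- unique(gm$pops)
    groups <- stats::setNames(as.list(labs), labs)
  }
  hap_by_group <- lapply(groups, function(g) haplotypes(gm, samples_of(gm, g)))
  gnames <- names(groups)
  pairs <- if (fst && length(gnames) > 1) utils::combn(gnames, 2, simplify = FALSE)
           else list()

  chroms <- unique(gm$chrom)
  if (is.null(chrom_len)) {
    chrom_len <- vapply(chroms, function(ch) max(gm$pos[gm$chrom == ch]), 0)
  }
  out <- list()
  for (ch in chroms) {
    idx <- which(gm$chrom == ch)
    pos <- gm$pos[idx]
    len <- chrom_len[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    df <- data.frame(chrom = ch, start = starts, end = ends)

    ## cumulative per-site quantities per group
    lo <- findInterval(df$start, pos) + 1L
    hi <- findInterval(df$end, pos)
    rsum <- function(x) {
      cs <- c(0, cumsum(x))
      cs[hi + 1L] - cs[lo]
    }
    wlen <- df$end - df$start
    cnt <- rsum(rep(1, length(pos)))
    gstats <- list()
    for (g in gnames) {
      h <- hap_by_group[[g]][idx, , drop = FALSE]
      sc <- site_counts(h)
      seg <- as.numeric(sc$n0 > 0 & sc$n1 > 0)
      usable <- sc$ns >= 2
      contrib <- ifelse(usable, 2 * sc$n0 * sc$n1 /
                          pmax(sc$ns * (sc$ns - 1), 1), 0)
      n <- ncol(h)
      S <- rsum(seg)
      kbar <- rsum(contrib)
      pi <- kbar / wlen
      tw <- S / (harmonic(n - 1) * wlen)
      k <- tajima_constants(n)
      D <- if (n == 2) ifelse(S > 0, 0, NA_real_) else
        ifelse(S > 0, (kbar - S / k$a1) /
                 sqrt(k$e1 * S + k$e2 * S * pmax(S - 1, 0)), NA_real_)
      ## a window holding variant records but no usable genotype gets the
      ## undefined sentinel; a window with no variant record at all is
      ## fully monomorphic (VCFs only store segregating sites), so pi = 0
      nodata <- rsum(as.numeric(usable)) == 0 & cnt > 0
      pi[nodata] <- NA_real_; tw[nodata] <- NA_real_; D[nodata] <- NA_real_
      df[[paste0("n_", g)]] <- n
      df[[paste0("S_", g)]] <- S
      df[[paste0("pi_", g)]] <- pi
      df[[paste0("tw_", g)]] <- tw
      df[[paste0("D_", g)]] <- D
      gstats[[g]] <- sc
    }
    for (pr in pairs) {
      s1 <- gstats[[pr[1]]]; s2 <- gstats[[pr[2]]]
      ok <- s1$ns >= 2 & s2$ns >= 2
      p1 <- ifelse(ok, s1$n1 / pmax(s1$ns, 1), 0)
      p2 <- ifelse(ok, s2$n1 / pmax(s2$ns, 1), 0)
      hw <- ifelse(ok, (s1$ns / pmax(s1$ns - 1, 1) * 2 * p1 * (1 - p1) +
                          s2$ns / pmax(s2$ns - 1, 1) * 2 * p2 * (1 - p2)) / 2, 0)
      hb <- ifelse(ok, p1 * (1 - p2) + p2 * (1 - p1), 0)
      sw <- rsum(hw); sb <- rsum(hb)
      df[[paste0("fst_", pr[1], "_", pr[2])]] <-
        ifelse(sb > 0, 1 - sw / sb, NA_real_)
    }
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Haplotype-based `r^2 = D^2 / (pA*(1-pA)*pB*(1-pB))` on complete
#' haplotype pairs (missing entries dropped pairwise).
#'
#' @param a,b haplotype vectors (0/1/NA) over the same haplotypes
#' @return r-squared in `[0, 1]`, or `NA` when either site is
#'   monomorphic among the complete pairs
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) return(NA_real_)
  pa <- mean(a); pb <- mean(b)
  va <- pa * (1 - pa); vb <- pb * (1 - pb)
  if (va == 0 || vb == 0) return(NA_real_)
  D <- mean(a * b) - pa * pb
  (D * D) / (va * vb)
}

## D' companion statistic (optional output of ld_decay)
ld_dprime <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) return(NA_real_)
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(a * b) - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax == 0) return(NA_real_)
  abs(D) / dmax
}

## Exact Hardy-Weinberg test p-value from diploid genotype counts
## (mid-free full enumeration; used only by the optional hwcutoff filter)
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (n == 0) return(1)
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(hets, function(h) {
    hom_a <- (n_a - h) / 2
    hom_b <- n - hom_a - h
    lfactorial(n) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b) +
      h * log(2) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
      lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Linkage-disequilibrium decay
#'
#' Mean r-squared per distance bin over all qualifying site pairs
#' within one population, with the conventions of a Haploview-style
#' scan: pairs at most `maxdist` apart, both sites at minor allele
#' frequency at least `min_maf`.  The half-decay distance is the
#' midpoint of the first bin whose mean r-squared drops to half the
#' maximum bin mean (or `NA` if never reached).
#'
#' @param gm a [genotype_matrix()]
#' @param pop population label(s) defining the sample subset
#' @param maxdist maximum pair distance in bp (default 250 kb)
#' @param min_maf minor-allele-frequency cutoff (default 0.1)
#' @param bin distance bin width in bp (default 1 kb)
#' @param hw_cutoff optional exact Hardy-Weinberg p-value cutoff below
#'   which sites are dropped.  Off (`NULL`) by default: Hardy-Weinberg
#'   equilibrium is violated by design in selfing species, so this
#'   filter would discard most genuine sites.
#' @param dprime also compute mean D' per bin (default `FALSE`)
#' @return list with `bins` (data frame: bin_start, bin_end, mean_r2,
#'   n_pairs, and optionally mean_dprime) and `half_decay` (bp or `NA`)
#' @export
ld_decay <- function(gm, pop, maxdist = 250000L, min_maf = 0.1,
                     bin = 1000L, hw_cutoff = NULL, dprime = FALSE) {
  samp <- samples_of(gm, pop)
  h <- haplotypes(gm, samp)
  keep <- rep(TRUE, n_sites(gm))
  sc <- site_counts(h)
  maf <- ifelse(sc$ns > 0, pmin(sc$n1, sc$n0) / pmax(sc$ns, 1), 0)
  keep <- keep & maf >= min_maf
  if (!is.null(hw_cutoff)) {
    g <- gm$geno[, samp, drop = FALSE]
    pvals <- vapply(seq_len(nrow(g)), function(i) {
      hwe_exact_p(sum(g[i, ] == 0L, na.rm = TRUE),
                  sum(g[i, ] == 1L, na.rm = TRUE),
                  sum(g[i, ] == 2L, na.rm = TRUE))
    }, 0)
    keep <- keep & pvals >= hw_cutoff
  }
  idx <- which(keep)
  nb <- as.integer(ceiling(maxdist / bin))
  bins <- data.frame(bin_start = (seq_len(nb) - 1L) * bin,
                     bin_end = seq_len(nb) * bin)
  acc_r2 <- numeric(nb); acc_n <- integer(nb); acc_dp <- numeric(nb)
  for (ch in unique(gm$chrom)) {
    ci <- idx[gm$chrom[idx] == ch]
    if (length(ci) < 2) next
    pos <- gm$pos[ci]
    for (a in seq_len(length(ci) - 1)) {
      b <- a + 1L
      while (b <= length(ci) && pos[b] - pos[a] <= maxdist) {
        r2 <- ld_r2(h[ci[a], ], h[ci[b], ])
        if (!is.na(r2)) {
          bi <- as.integer(ceiling((pos[b] - pos[a]) / bin))
          acc_r2[bi] <- acc_r2[bi] + r2
          acc_n[bi] <- acc_n[bi] + 1L
          if (dprime) {
            dp <- ld_dprime(h[ci[a], ], h[ci[b], ])
            if (!is.na(dp)) acc_dp[bi] <- acc_dp[bi] + dp
          }
        }
        b <- b + 1L
      }
    }
  }
  bins$mean_r2 <- ifelse(acc_n > 0, acc_r2 / acc_n, NA_real_)
  bins$n_pairs <- acc_n
  if (dprime) bins$mean_dprime <- ifelse(acc_n > 0, acc_dp / acc_n, NA_real_)
  occupied <- which(acc_n > 0)
  half_decay <- NA_real_
  if (length(occupied)) {
    mx <- max(bins$mean_r2[occupied])
    hit <- occupied[bins$mean_r2[occupied] <= mx / 2]
    if (length(hit))
      half_decay <- (bins$bin_start[hit[1]] + bins$bin_end[hit[1]]) / 2
  }
  list(bins = bins, half_decay = half_decay)
}

#' Partition samples into haplogroups over a region
#'
#' Groups samples by exact identity of their genotype vectors over the
#' region's sites.  Missing calls act as wildcards: a sample compatible
#' with more than one existing group joins the largest (ties to the
#' first-created group), and the group consensus absorbs its observed
#' calls.  Groups are returned ordered by size.
#'
#' @param gm a [genotype_matrix()]
#' @param chrom chromosome id
#' @param start,end region bounds, 0-based half-open
#' @param samples optional sample subset (default: all)
#' @return list of character vectors of sample ids, largest first
#' @export
haplogroup_partition <- function(gm, chrom, start, end, samples = NULL) {
  if (is.null(samples)) samples <- gm$samples
  in_region <- gm$chrom == chrom & gm$pos > start & gm$pos <= end
  if (!any(in_region)) abort("haplogroup_partition(): region contains no genotyped site")
  g <- gm$geno[in_region, samples, drop = FALSE]
  groups <- list()      # member sample ids
  consensus <- list()   # per-group consensus vectors
  compatible <- function(v, w) {
    both <- !is.na(v) & !is.na(w)
    all(v[both] == w[both])
  }
  for (s in samples) {
    v <- g[, s]
    hits <- which(vapply(consensus, compatible, TRUE, v = v))
    if (!length(hits)) {
      groups[[length(groups) + 1L]] <- s
      consensus[[length(consensus) + 1L]] <- v
    } else {
      sizes <- lengths(groups)[hits]
      pick <- hits[which.max(sizes)]  # which.max takes the first on ties
      groups[[pick]] <- c(groups[[pick]], s)
      cv <- consensus[[pick]]
      fill <- is.na(cv) & !is.na(v)
      cv[fill] <- v[fill]
      consensus[[pick]] <- cv
    }
  }
  groups[order(lengths(groups), decreasing = TRUE)]
}
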