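## Synthetic-data generator: coalescent windows, Balding-Nichols two-population
## genotypes, and full wild/landrace/elite panels with planted sweeps and CNVs.

#' Simulate one neutral coalescent window
#'
#' Standard Kingman coalescent with infinite-sites mutation.  While `k`
#' lineages remain, the waiting time to the next coalescence is
#' exponential with rate `choose(k, 2)`; mutations fall on the genealogy
#' as a Poisson process with rate `theta * L / 2` per unit branch
#' length, each at a fresh uniformly drawn base position (collisions are
#' redrawn so every site stays biallelic).
#'
#' @param n number of haploid samples (>= 2)
#' @param theta scaled per-site mutation rate (> 0)
#' @param L window length in bp (>= 1)
#' @param seed optional RNG seed; if `NULL` the current RNG state is used
#' @return list with `haps` (n x S binary matrix; 1 = derived allele)
#'   and `pos` (sorted 1-based positions within the window)
#' @examples
#' w <- simulate_coalescent_window(10, 0.002, 50000, seed = 1)
#' ncol(w$haps) # segregating sites
#' @export
simulate_coalescent_window <- function(n, theta, L, seed = NULL) {
  if (!is_count(n) || n < 2) abort("simulate_coalescent_window(): n must be >= 2")
  if (!is.finite(theta) || theta <= 0) abort("simulate_coalescent_window(): theta must be > 0")
  if (!is_count(L) || L < 1) abort("simulate_coalescent_window(): L must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  ## genealogy: record, per edge, its subtended leaf set and length
  k <- n
  t_now <- 0
  leafsets <- lapply(seq_len(n), identity)
  birth <- numeric(n)
  edge_sets <- vector("list", 2L * (n - 1L))
  edge_len <- numeric(2L * (n - 1L))
  e <- 0L
  while (k > 1L) {
    t_now <- t_now + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    for (j in pair) {
      e <- e + 1L
      edge_sets[[e]] <- leafsets[[j]]
      edge_len[e] <- t_now - birth[j]
    }
    merged <- c(leafsets[[pair[1L]]], leafsets[[pair[2L]]])
    keep <- setdiff(seq_len(k), pair)
    leafsets <- c(leafsets[keep], list(merged))
    birth <- c(birth[keep], t_now)
    k <- k - 1L
  }
  edge_sets <- edge_sets[seq_len(e)]
  edge_len <- edge_len[seq_len(e)]

  total_len <- sum(edge_len)
  n_mut <- stats::rpois(1L, theta * L / 2 * total_len)
  n_mut <- min(n_mut, L)  # infinite-sites cannot exceed available bases
  if (n_mut == 0L) {
    return(list(haps = matrix(0L, n, 0L), pos = integer(0)))
  }
  mut_edge <- sample.int(e, n_mut, replace = TRUE, prob = edge_len)
  ## fresh position per mutation; redraw on collision
  pos <- integer(n_mut)
  used <- integer(0)
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample.int(L, 1L)
      if (!(p %in% used)) break
    }
    pos[i] <- p
    used <- c(used, p)
  }
  haps <- matrix(0L, n, n_mut)
  for (i in seq_len(n_mut)) haps[edge_sets[[mut_edge[i]]], i] <- 1L
  ord <- order(pos)
  list(haps = haps[, ord, drop = FALSE], pos = pos[ord])
}

#' Simulate two diverged populations under the Balding-Nichols model
#'
#' Per site, an ancestral allele frequency `p` is drawn from
#' Uniform(0.05, 0.95); each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is `p` and whose spread is
#' governed by the divergence parameter `F` (the expected Fst).  At
#' `F = 0` the Beta degenerates and both populations keep frequency `p`
#' exactly.  Haploid alleles are then Bernoulli draws per sample.
#'
#' @param n_per_pop haploid samples per population
#' @param n_sites number of sites (>= 1)
#' @param F divergence parameter in `[0, 1)`
#' @param seed optional RNG seed
#' @return list with `haps` (2*n_per_pop x n_sites 0/1 matrix), `pop`
#'   (population label per row), and the per-site frequencies `p`,
#'   `p1`, `p2`
#' @export
simulate_balding_nichols <- function(n_per_pop, n_sites, F, seed = NULL) {
  if (!is_count(n_per_pop) || n_per_pop < 1) abort("n_per_pop must be >= 1")
  if (!is_count(n_sites) || n_sites < 1) abort("n_sites must be >= 1")
  if (!is.finite(F) || F < 0 || F >= 1) abort("F must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n_sites, 0.05, 0.95)
  if (F == 0) {
    p1 <- p
    p2 <- p
  } else {
    scale <- (1 - F) / F
    p1 <- stats::rbeta(n_sites, p * scale, (1 - p) * scale)
    p2 <- stats::rbeta(n_sites, p * scale, (1 - p) * scale)
  }
  h1 <- matrix(stats::rbinom(n_per_pop * n_sites, 1L, rep(p1, each = n_per_pop)),
               n_per_pop, n_sites)
  h2 <- matrix(stats::rbinom(n_per_pop * n_sites, 1L, rep(p2, each = n_per_pop)),
               n_per_pop, n_sites)
  list(haps = rbind(h1, h2),
       pop = rep(c("pop1", "pop2"), each = n_per_pop),
       p = p, p1 = p1, p2 = p2)
}

#' Configuration for a synthetic resequencing panel
#'
#' Defaults mirror the structure of a wild/landrace/elite soybean
#' resequencing panel: 7 wild, 43 landrace and 56 elite inbred lines;
#' per-site diversity ordered wild > landrace > elite (2.79, 1.78 and
#' 1.60 per kb); mean sequencing depth 17x.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs
#' @param n_wild,n_landrace,n_elite line counts per population
#' @param L chromosome length in bp
#' @param n_chrom number of chromosomes (named chr1, chr2, ...)
#' @param theta_wild,theta_landrace,theta_elite per-site scaled mutation
#'   rates
#' @param sweep_regions data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `reduction` in (0, 1], and optionally `pops`
#'   (comma-separated populations whose theta is reduced; default
#'   landrace+elite, the cultivated pool).  Regions must not overlap.
#' @param fst_model_F divergence parameter for [simulate_balding_nichols()]
#' @param het_rate residual heterozygosity probability per genotype
#' @param miss_rate missingness probability per genotype
#' @param cnv_truth data frame with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open), `fold` (e.g. 0.3 for a loss, 2.5 for a
#'   gain); intervals must not overlap within a sample
#' @param mean_depth expected read depth (x)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_wild = 7L, n_landrace = 43L, n_elite = 56L,
                       L = 1e6, n_chrom = 1L,
                       theta_wild = 2.79e-3, theta_landrace = 1.78e-3,
                       theta_elite = 1.60e-3,
                       sweep_regions = NULL, fst_model_F = 0.3,
                       het_rate = 0.01, miss_rate = 0.05,
                       cnv_truth = NULL, mean_depth = 17) {
  rates <- c(het_rate = het_rate, miss_rate = miss_rate)
  if (any(rates < 0 | rates > 1)) abort("sim_config(): rates must lie in [0, 1]")
  if (fst_model_F < 0 || fst_model_F >= 1) abort("sim_config(): fst_model_F must lie in [0, 1)")
  thetas <- c(theta_wild, theta_landrace, theta_elite)
  if (any(!is.finite(thetas) | thetas <= 0)) abort("sim_config(): thetas must be > 0")
  if (!is.null(sweep_regions)) {
    sweep_regions <- as.data.frame(sweep_regions)
    if (is.null(sweep_regions$pops)) sweep_regions$pops <- "landrace,elite"
    if (is.null(sweep_regions$reduction)) abort("sweep_regions needs a 'reduction' column")
    if (any(sweep_regions$reduction <= 0 | sweep_regions$reduction > 1))
      abort("sweep reduction factors must lie in (0, 1]")
    if (any(sweep_regions$start < 0 | sweep_regions$end > L))
      abort("sweep regions must lie within [0, L)")
    for (ch in unique(sweep_regions$chrom)) {
      r <- sweep_regions[sweep_regions$chrom == ch, ]
      r <- r[order(r$start), ]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
        abort("sweep regions overlap on %s", ch)
    }
  }
  if (!is.null(cnv_truth)) {
    cnv_truth <- as.data.frame(cnv_truth)
    for (key in unique(paste(cnv_truth$sample, cnv_truth$chrom))) {
      r <- cnv_truth[paste(cnv_truth$sample, cnv_truth$chrom) == key, ]
      r <- r[order(r$start), ]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
        abort("cnv_truth intervals overlap within a sample track")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_wild = n_wild, n_landrace = n_landrace, n_elite = n_elite,
                 L = as.integer(L), n_chrom = as.integer(n_chrom),
                 theta = c(wild = theta_wild, landrace = theta_landrace,
                           elite = theta_elite),
                 sweep_regions = sweep_regions, fst_model_F = fst_model_F,
                 het_rate = het_rate, miss_rate = miss_rate,
                 cnv_truth = cnv_truth, mean_depth = mean_depth),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d wild + %d landrace + %d elite lines\n",
              x$n_wild, x$n_landrace, x$n_elite))
  cat(sprintf("  genome: %d chromosome(s) x %d bp; seed %d\n",
              x$n_chrom, x$L, x$seed))
  cat(sprintf("  theta (per site): wild %.2e, landrace %.2e, elite %.2e\n",
              x$theta["wild"], x$theta["landrace"], x$theta["elite"]))
  cat(sprintf("  %d sweep region(s), %d planted CNV(s)\n",
              if (is.null(x$sweep_regions)) 0L else nrow(x$sweep_regions),
              if (is.null(x$cnv_truth)) 0L else nrow(x$cnv_truth)))
  invisible(x)
}

## Random DNA of length n as a character string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random CDS of n_codons codons: ATG start, TAA stop, no internal stops
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(Biostrings::GENETIC_CODE)
  internal <- sample(setdiff(codons, stops), n_codons - 2L, replace = TRUE)
  paste(c("ATG", internal, "TAA"), collapse = "")
}

## Fixed toy gene architecture used by the panel generator (lengths in bp).
## exon1 = 200 UTR5 + 150 CDS; intron 300; exon2 = 300 CDS; intron 300;
## exon3 = 150 CDS + 200 UTR3.  CDS total 600 bp (200 codons).
GENE_SPAN <- 200 + 150 + 300 + 300 + 300 + 150 + 200

place_gene <- function(gene_id, chrom, start0, strand) {
  ## start0: 0-based genomic start of the gene span; returns feature table
  ## with 1-based inclusive coordinates (GFF3 convention)
  seg_len <- c(utr5 = 200L, cds1 = 150L, int1 = 300L, cds2 = 300L,
               int2 = 300L, cds3 = 150L, utr3 = 200L)
  ends <- cumsum(seg_len)
  starts <- ends - seg_len + 1L
  g <- function(i) c(start0 + starts[[i]], start0 + ends[[i]])
  feat <- rbind(
    data.frame(type = "five_prime_UTR", start = g("utr5")[1], end = g("utr5")[2]),
    data.frame(type = "CDS", start = g("cds1")[1], end = g("cds1")[2]),
    data.frame(type = "CDS", start = g("cds2")[1], end = g("cds2")[2]),
    data.frame(type = "CDS", start = g("cds3")[1], end = g("cds3")[2]),
    data.frame(type = "three_prime_UTR", start = g("utr3")[1], end = g("utr3")[2]))
  if (strand == "-") {
    ## mirror roles: on the minus strand the 5' UTR sits at the high end
    feat$type <- rev(feat$type)
  }
  ## exon1 spans utr5+cds1, exon2 = cds2, exon3 spans cds3+utr3
  exons <- data.frame(
    type = "exon",
    start = start0 + c(starts[["utr5"]], starts[["cds2"]], starts[["cds3"]]),
    end = start0 + c(ends[["cds1"]], ends[["cds2"]], ends[["utr3"]]))
  rbind(data.frame(type = "gene", start = start0 + 1L, end = start0 + ends[["utr3"]]),
        data.frame(type = "mRNA", start = start0 + 1L, end = start0 + ends[["utr3"]]),
        exons, feat) |> transform(gene = gene_id, chrom = chrom, strand = strand)
}

#' Simulate a full wild/landrace/elite resequencing panel
#'
#' Tiles each chromosome into simulation windows and draws an
#' independent coalescent genealogy per population per window (no
#' recombination within a window, free recombination between windows).
#' Inside a planted sweep region the selected populations' theta is
#' multiplied by the region's `reduction` factor.  Haploid outputs are
#' doubled to homozygous diploid genotypes, then residual
#' heterozygosity and missingness are injected at the configured rates.
#' Toy gene models (three exons, both strands, UTRs, valid ORFs pasted
#' into the reference) and per-sample binned depth tracks with planted
#' CNV folds complete the panel.
#'
#' @param config a [sim_config()] object
#' @param outdir optional directory; when given, VCF / GFF3 / FASTA /
#'   population TSV / depth TSV / truth tables are written there
#' @param sim_window coalescent window size in bp (default 50 kb)
#' @param what components to generate: any of `"variants"`, `"genes"`,
#'   `"depth"`
#' @param gene_spacing distance between consecutive gene starts in bp
#' @param depth_bin depth-track bin width in bp
#' @return list with `gm` (a [genotype_matrix()]), `genes` (feature
#'   table), `ref` (a `DNAStringSet`), `depth` (binned depth track data
#'   frame), `truth` (planted sweep/CNV/theta tables), and `files`
#'   (paths, when `outdir` was given)
#' @export
simulate_panel <- function(config, outdir = NULL, sim_window = 50000L,
                           what = c("variants", "genes", "depth"),
                           gene_spacing = 25000L, depth_bin = 500L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  what <- match.arg(what, several.ok = TRUE)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  L <- config$L

  samples <- c(sprintf("wild_%02d", seq_len(config$n_wild)),
               sprintf("landrace_%02d", seq_len(config$n_landrace)),
               sprintf("elite_%02d", seq_len(config$n_elite)))
  pops <- rep(c("wild", "landrace", "elite"),
              c(config$n_wild, config$n_landrace, config$n_elite))
  n_by_pop <- stats::setNames(c(config$n_wild, config$n_landrace, config$n_elite),
                              c("wild", "landrace", "elite"))

  ## reference sequences kept as plain strings while being edited; only
  ## needed when alleles, gene ORFs or output files are requested
  need_ref <- any(c("variants", "genes") %in% what) || !is.null(outdir)
  ref_seq <- if (need_ref) {
    stats::setNames(vapply(chroms, function(ch) random_dna(L), ""), chroms)
  } else NULL

  ## gene models, ORFs pasted into the reference
  genes <- NULL
  if ("genes" %in% what) {
    rows <- list()
    gid <- 0L
    for (ch in chroms) {
      starts0 <- seq(2000L, L - GENE_SPAN - 2000L, by = gene_spacing)
      for (s0 in starts0) {
        gid <- gid + 1L
        strand <- if (gid %% 2L == 1L) "+" else "-"
        ft <- place_gene(sprintf("gene%04d", gid), ch, s0, strand)
        rows[[length(rows) + 1L]] <- ft
        ## paste a valid ORF over the CDS segments (coding-strand order)
        cds <- ft[ft$type == "CDS", ]
        cds <- cds[order(cds$start, decreasing = (strand == "-")), ]
        orf <- random_cds(200L)
        if (strand == "-")
          orf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
        ## orf is now in genomic (plus-strand) orientation over the CDS,
        ## low coordinates first
        cds <- cds[order(cds$start), ]
        off <- 0L
        for (i in seq_len(nrow(cds))) {
          w <- cds$end[i] - cds$start[i] + 1L
          substr(ref_seq[[ch]], cds$start[i], cds$end[i]) <-
            substring(orf, off + 1L, off + w)
          off <- off + w
        }
      }
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
  }

  ## variant simulation, window by window
  gm <- NULL
  theta_truth <- NULL
  if ("variants" %in% what) {
    site_chrom <- character(0); site_pos <- integer(0)
    geno_rows <- list()
    th_rows <- list()
    for (ch in chroms) {
      win_starts <- seq(0L, L - 1L, by = sim_window)
      for (ws in win_starts) {
        we <- min(ws + sim_window, L)
        wlen <- we - ws
        used <- integer(0)
        win_pos <- integer(0)
        win_cols <- list()  # per site: list(pop, carrier haplotype indices)
        for (pop in names(n_by_pop)) {
          th <- config$theta[[pop]]
          sr <- config$sweep_regions
          if (!is.null(sr)) {
            hit <- sr$chrom == ch & sr$start < we & sr$end > ws
            if (any(hit)) {
              red <- sr$reduction[hit][1L]
              in_pops <- strsplit(sr$pops[hit][1L], ",")[[1L]]
              if (pop %in% trimws(in_pops)) th <- th * red
            }
          }
          th_rows[[length(th_rows) + 1L]] <-
            data.frame(chrom = ch, start = ws, end = we, pop = pop, theta = th)
          w <- simulate_coalescent_window(n_by_pop[[pop]], th, wlen)
          if (length(w$pos) == 0L) next
          gpos <- ws + w$pos  # 1-based within chromosome
          ## resolve collisions with sites already drawn by another pop
          for (i in seq_along(gpos)) {
            while (gpos[i] %in% used) {
              gpos[i] <- ws + sample.int(wlen, 1L)
            }
            used <- c(used, gpos[i])
          }
          for (i in seq_along(gpos)) {
            win_pos <- c(win_pos, gpos[i])
            win_cols[[length(win_cols) + 1L]] <-
              list(pop = pop, carriers = which(w$haps[, i] == 1L))
          }
        }
        if (length(win_pos) == 0L) next
        g <- matrix(0L, length(win_pos), length(samples))
        for (i in seq_along(win_pos)) {
          pop <- win_cols[[i]]$pop
          cols <- which(pops == pop)[win_cols[[i]]$carriers]
          g[i, cols] <- 2L
        }
        ord <- order(win_pos)
        site_chrom <- c(site_chrom, rep(ch, length(win_pos)))
        site_pos <- c(site_pos, win_pos[ord])
        geno_rows[[length(geno_rows) + 1L]] <- g[ord, , drop = FALSE]
      }
    }
    geno <- if (length(geno_rows)) do.call(rbind, geno_rows)
            else matrix(0L, 0L, length(samples))
    ## residual heterozygosity, then missingness
    nc <- length(geno)
    if (nc > 0 && config$het_rate > 0) {
      flip <- stats::runif(nc) < config$het_rate
      geno[flip] <- 1L
    }
    if (nc > 0 && config$miss_rate > 0) {
      drop <- stats::runif(nc) < config$miss_rate
      geno[drop] <- NA_integer_
    }
    ## alleles from the reference; alt drawn among the other three bases
    ref_al <- alt_al <- character(length(site_pos))
    if (length(site_pos)) {
      for (ch in unique(site_chrom)) {
        idx <- which(site_chrom == ch)
        ref_al[idx] <- substring(ref_seq[[ch]], site_pos[idx], site_pos[idx])
      }
      bases <- c("A", "C", "G", "T")
      shift <- sample.int(3L, length(ref_al), replace = TRUE)
      alt_al <- bases[(match(ref_al, bases) - 1L + shift) %% 4L + 1L]
    }
    gm <- genotype_matrix(site_chrom, site_pos, ref_al, alt_al, geno,
                          samples, pops)
    theta_truth <- do.call(rbind, th_rows)
  }

  ## depth tracks with planted CNVs
  depth <- NULL
  if ("depth" %in% what) {
    rows <- list()
    for (ch in chroms) {
      bstart <- seq(0L, L - 1L, by = depth_bin)
      bend <- pmin(bstart + depth_bin, L)
      mid <- (bstart + bend) / 2
      for (s in samples) {
        fold <- rep(1, length(bstart))
        ct <- config$cnv_truth
        if (!is.null(ct)) {
          r <- ct[ct$sample == s & ct$chrom == ch, ]
          for (i in seq_len(nrow(r)))
            fold[mid >= r$start[i] & mid < r$end[i]] <- r$fold[i]
        }
        ## noise scales with the local expected coverage, as sampling
        ## noise in real depth tracks does
        d <- stats::rnorm(length(bstart), config$mean_depth * fold,
                          0.15 * config$mean_depth * fold)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = bstart, end = bend,
          depth = round(pmax(d, 0), 3))
      }
    }
    depth <- do.call(rbind, rows)
  }

  truth <- list(sweeps = config$sweep_regions, cnv = config$cnv_truth,
                window_theta = theta_truth)
  ref <- if (need_ref) Biostrings::DNAStringSet(ref_seq) else NULL
  out <- list(gm = gm, genes = genes, ref = ref, depth = depth,
              truth = truth,
              pops = data.frame(sample = samples, group = pops))
  if (!is.null(outdir)) out$files <- write_panel(out, outdir)
  invisible(out)
}

## Write every panel component as plain-text files; deterministic bytes.
write_panel <- function(panel, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  if (!is.null(panel$gm)) {
    files$vcf <- file.path(outdir, "panel.vcf")
    write_vcf(panel$gm, files$vcf)
  }
  files$pops <- file.path(outdir, "populations.tsv")
  utils::write.table(panel$pops, files$pops, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files$fasta <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(panel$ref, files$fasta)
  if (!is.null(panel$genes)) {
    files$gff <- file.path(outdir, "genes.gff3")
    write_gff3(panel$genes, files$gff)
  }
  if (!is.null(panel$depth)) {
    files$depth <- file.path(outdir, "depth.tsv")
    utils::write.table(panel$depth, files$depth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tr <- panel$truth
  if (!is.null(tr$sweeps)) {
    files$truth_sweeps <- file.path(outdir, "truth_sweeps.tsv")
    utils::write.table(tr$sweeps, files$truth_sweeps, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tr$cnv)) {
    files$truth_cnv <- file.path(outdir, "truth_cnv.tsv")
    utils::write.table(tr$cnv, files$truth_cnv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tr$window_theta)) {
    files$truth_theta <- file.path(outdir, "truth_window_theta.tsv")
    utils::write.table(tr$window_theta, files$truth_theta, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  files
}

## GFF3 writer for the simulator's feature table (1-based inclusive input).
## Deliberately minimal and byte-deterministic.
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(genes$gene)) {
    ft <- genes[genes$gene == g, ]
    ft <- ft[order(match(ft$type, c("gene", "mRNA", "exon", "five_prime_UTR",
                                    "CDS", "three_prime_UTR")), ft$start), ]
    tid <- paste0(g, ".t1")
    attr_of <- function(type) {
      switch(type,
             gene = paste0("ID=", g),
             mRNA = paste0("ID=", tid, ";Parent=", g),
             paste0("Parent=", tid))
    }
    phase <- rep(".", nrow(ft))
    is_cds <- ft$type == "CDS"
    if (any(is_cds)) {
      cds <- ft[is_cds, ]
      ord <- order(cds$start, decreasing = (cds$strand[1] == "-"))
      len <- (cds$end - cds$start + 1L)[ord]
      ph <- (3L - (cumsum(c(0L, len[-length(len)])) %% 3L)) %% 3L
      phase[which(is_cds)[ord]] <- ph
    }
    writeLines(sprintf("%s\tpopsweep\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       ft$chrom, ft$type, ft$start, ft$end, ft$strand,
                       phase, vapply(ft$type, attr_of, "")), con)
  }
  invisible(path)
}
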