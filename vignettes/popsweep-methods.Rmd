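---
title: "Diversity scans and sweep detection in inbred panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity scans and sweep detection in inbred panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

popsweep implements the analysis stack used in crop resequencing
studies of domestication: quality-filter a multi-sample SNP set,
annotate functional effects, profile diversity in sliding windows,
and scan for regions where cultivated material has lost the diversity
its wild relatives retain.  This vignette is the package's own account
of the statistical choices involved, including every place where the
procedure admits more than one reasonable reading and which reading the
package takes.

## The data model

The central object is the `genotype_matrix`: biallelic SNP sites by
samples, genotypes coded 0 (hom-ref), 1 (het), 2 (hom-alt), `NA`
(missing), with a population label (`wild`, `landrace`, `elite`, or any
other label set) per sample.  Indels of 1–5 bp net length change travel
in a parallel table.  Coordinates are 1-based inclusive on VCF/GFF3
input and output, 0-based half-open internally and in BED/window
output; this convention is stated once here and enforced by tests.

**Inbred haplotype encoding.**  The panels this package targets are
selfing species; lines are nearly fully homozygous and residual
heterozygosity is largely genotyping noise or recent outcrossing.  All
diversity and LD statistics therefore use one haplotype per line:
hom-ref maps to allele 0, hom-alt to allele 1, and heterozygous calls
are set to missing.  This avoids the haplotype-phasing step that
diploid LD software performs internally and matches how diversity in
such panels is conventionally computed.  The cost is that genuinely
heterozygous regions (recent crosses, paralogous collapse) are
underweighted.

## Site filters

Defaults follow the published pipeline: aggregate depth strictly
between 50x and 3000x, consensus quality strictly above 15, copy
number strictly below 1.5, then removal of sites whose heterozygote
ratio or missing ratio exceeds 0.88.  Two readings were open:

* **Boundary semantics.**  All thresholds are strict, exactly as
  printed (`> 50x`, `< 3000x`, `> 15`, `< 1.5`, "larger than 0.88");
  a value exactly at a bound fails the depth/quality/copy gates and
  passes the ratio gates.  Tests pin this behaviour.
* **Ratio denominators.**  The heterozygote ratio is heterozygous
  calls over *non-missing* calls — the only denominator that stays
  well defined under high missingness — while the missing ratio is
  missing calls over *all* samples.  Both thresholds are unusually
  permissive (0.88); they are exposed as `filter_config()` fields
  rather than second-guessed.

Multi-allelic records are dropped, not split: every downstream
statistic assumes biallelic sites.

## Effect annotation

Context classification uses the precedence cds > utr5 > utr3 >
intron > intergenic for the per-site summary, while every spanning
transcript also receives its own call (overlapping transcripts are
annotated independently, so per-class counts can legitimately exceed
the per-site summary totals).  Coding effects translate reference and
alternate codons with the standard nuclear code, reverse-complemented
for minus-strand transcripts.  Design choices:

* **Splice sites** are the first/last 2 bp of an intron — the
  canonical GT/AG dinucleotides — since no wider definition is
  implied anywhere; the window is a flag (`splice_window`).
* **Start loss** is evaluated only at the annotated initiator ATG;
  downstream in-frame ATGs are ignored.
* **4-fold degenerate sites** must be 4-fold in *every* transcript
  whose CDS covers them.  These sites serve as a quasi-neutral marker
  panel, so the conservative intersection is the appropriate rule; a
  site synonymous in one transcript but constrained in an overlapping
  one is not neutral.
* Transcripts whose CDS length is not divisible by 3 are excluded
  from coding-effect calls with a warning rather than silently
  mistranslated.

An exhaustive oracle test checks all 64 codons x 9 single-base
substitutions (576 cases) against direct codon-table translation.

## Window statistics

Windows are 50 kb every 5 kb, anchored at coordinate 0 per chromosome,
trailing partial window included.  Both appear in practice — 50-kb
non-overlapping and 5-kb-step sliding — and the package supports any
(window, step) pair; the 5-kb step is the default because the sweep
scan uses it.

Per window and population: S, θ~π~ (mean pairwise difference with
pairwise deletion of missing data, divided by window length), θ~w~ =
S / (a~n−1~ L), and Tajima's D with the canonical 1989 constants.
Conventions for degenerate cases:

* θ values are per site (divide by window bp), matching the magnitude
  at which panel diversities are reported (around 10^-3^).
* A window holding variant records but no usable genotype emits `NA`
  sentinels, distinguishing "no data" from "no diversity"; a window
  with no variant record at all is genuinely monomorphic (VCFs store
  only segregating sites) and reports θ = 0.
* Tajima's D at S = 0 is the `NA` sentinel, not an error.  At n = 2
  the numerator is identically zero and the normalising constants
  vanish; D is defined as 0 there.

**F~ST~.**  No estimator is named in the source procedure, so the
package uses Hudson's estimator in the Bhatia ratio-of-averages form,
1 − mean(H~w~)/mean(H~b~), with the n/(n−1) unbiased within-population
heterozygosity.  Hudson's form is preferred for its robustness to very
unequal sample sizes (e.g. 7 wild lines against 56 elite).  Negative
estimates are possible and reported as computed.  Windows where mean
H~b~ = 0 return the `NA` sentinel.

**LD decay.**  Pairwise haplotype r² with the usual gates: both sites
at MAF ≥ 0.1, pair distance ≤ 250 kb, means per 1-kb distance bin.
The half-decay distance is the midpoint of the first bin whose mean
drops to half the maximum bin mean (`NA` if never reached).  Two
Haploview-inherited options are present but off by default: an exact
Hardy–Weinberg filter (`hw_cutoff`) — off because HWE is violated by
design in a selfing species and would discard most genuine sites —
and a D′ column (`dprime`).

## The sweep scan

The scan is the plain diversity ratio — deliberately not a
composite-likelihood method: per window,
π~diverse~/π~selected~, where the selected group for the domestication
contrast is the pooled landrace+elite gene pool and for the artificial
selection contrast is the elite group alone.  Steps and the decisions
inside them:

1. Windows with undefined π in either group are dropped (logged).
   π~selected~ = 0 with π~diverse~ > 0 yields an infinite ratio,
   ranked above all finite ratios; ties among infinities break by
   higher π~diverse~ (more power), then by coordinate.
2. Windows with π~diverse~ < 0.002 are removed *before* the quantile
   cut, following the stated order of operations.  The filter applies
   to the diverse group in both contrasts (wild, or landrace), by
   analogy; it is exposed as `min_pi`.
3. The top 5 % of the retained windows are selected:
   `ceiling(0.05 * n)` windows, with any window tied at the cutoff
   ratio also kept, so the rule is deterministic and order-free.
4. Selected windows that overlap or sit ≤ 50 kb apart (end-to-start
   gap) merge into one locus.  With 50-kb windows at a 5-kb step,
   "distance" must mean the end-to-start gap — any other reading
   merges everything.  Merging is idempotent and independent of input
   order (tested).
5. A gene overlaps a locus if their spans intersect by ≥ 1 bp.  The
   summary reports locus count, summed span, unique gene count, and —
   only if the caller supplies a genome size — the span percentage:
   published figures for the same span differ depending on the genome
   denominator used, so the package reports raw bp and leaves the
   denominator to the user.

## Depth-based CNV calling

Per sample, 500-bp bins are flagged where mean depth is strictly below
half or strictly above double the sample's genome-wide mean (binning
is a tractability choice; the bin width is a parameter).  The
published "initial and final minimum probability to merge adjacent
breakpoints" (0.5 / 0.8) is not defined anywhere; the package
interprets it as flagged-bin fractions in a two-pass merge: a
permissive pass joins same-type runs across gaps while the joined
span stays ≥ 0.5 flagged, a strict pass retains segments that are
≥ 0.8 flagged and strictly longer than 2 kb.  This interpretation is
documented as such and both thresholds are parameters.  Genome-wide
normalisation is the default (per-chromosome by flag); calls are
invariant to rescaling a whole track.  One practical consequence of
genome-wide normalisation, visible in the tests: planted CNVs must be
a small fraction of the genome, or they drag the mean itself.

## The synthetic-data generator

The generator's role is to produce data with exactly the statistical
structure the estimators assume, plus truth tables for recovery tests.
It is not a demographic model of soybean: the source study resequenced
real lines and gives no generative model, so every choice here is
acceptance-surface engineering, documented as such.

* **Within-population variation** comes from a standard Kingman
  coalescent per 50-kb window with infinite-sites mutation (collisions
  redrawn so sites stay biallelic): exponential coalescence times with
  rate C(k,2), mutations Poisson with rate θL/2 per unit branch
  length.  E[S] = θ L a~n−1~ and E[θ~π~] = θ, which the calibration
  tests verify to within 3 standard errors over 200 windows (n = 20,
  θ = 0.002, L = 50 kb), with mean Tajima's D in [−0.2, 0.2].
* **Populations are independent per window** — no shared genealogy
  between groups.  This suffices for testing the ratio scan and the
  estimators, and it inflates between-group divergence relative to a
  split model (every derived allele is private to its group unless
  shared by chance).  Realistic F~ST~ structure is therefore delegated
  to the separate Balding–Nichols generator, whose per-site
  frequencies are Beta-distributed around a shared ancestral frequency
  with E[F~ST~] ≈ F (recovered within ±0.05 at F = 0.3 in the tests).
  Window F~ST~ between independently simulated groups should *not* be
  read as calibrated.
* **Default panel composition** is 7 wild / 43 landrace / 56 elite
  lines at 17x depth with per-site θ of 2.79, 1.78 and 1.60 x 10^-3^
  — the configuration and diversity ordering of the motivating study.
  Residual heterozygosity is injected i.i.d. at 1% and missingness at
  5% by default: inbred lines are modelled as doubled haploids rather
  than by simulating selfing generations, and a 5% missing rate is
  typical of the ~17x short-read genotype matrices this emulates.
* **Sweeps** are planted by multiplying the selected populations'
  θ inside the region by the configured reduction factor (default
  target populations: landrace+elite).
* **Gene models** are toy three-exon genes with UTRs on alternating
  strands, their ORFs (ATG, no internal stops, TAA) pasted into the
  emitted reference so annotation is self-consistent.
* **Depth tracks** are Gaussian around mean_depth x fold with
  standard deviation 15% of the *local* expected depth — sampling
  noise in real coverage grows with coverage, and a constant-sd model
  would make gains far noisier than losses in normalised units.
  Planted CNV folds default to 0.3 / 2.5.
* With a fixed seed every emitted file is byte-identical across runs;
  the VCF and GFF3 writers deliberately emit no date stamps.

What passing the recovery tests does **not** show: performance on real
data with linked selection, recombination gradients, population
structure within groups, reference bias, or depth artefacts
(GC waves, mappability) — none of which the generator emulates.

## Problem sizes and runtime choices

The test suite and the acceptance script use: 200 neutral windows for
estimator calibration; 5,000 sites x 50 haploids per population for
F~ST~ recovery; ten seeds of a 10-Mb, 60-line panel with five planted
150-kb sweeps (reduction 0.05, θ~wild~ = 0.003) for sweep recovery —
the scan recovers ≥ 4/5 sweeps with ≤ 3 false loci in ≥ 8/10 seeds —
and fifty replicates of four planted 3–20 kb CNVs on a 2 x 1 Mb
two-chromosome genome for CNV recovery (boundary error ≤ 1 bin in
≥ 90% of plants).  These sizes keep a full run in a couple of minutes
on one core while leaving each experiment enough replication for its
stated tolerance.

## Known limitations

* The sweep scan is the plain π ratio; no composite-likelihood or
  haplotype-based statistics (that is a scope decision, not an
  oversight).
* Fst between independently simulated populations of the panel
  generator is a by-product, not a calibrated quantity.
* The CNV caller has no breakpoint refinement below bin resolution
  and no HMM smoothing; very short or low-contrast events near the
  0.5x/2.0x thresholds are missed by design of the strict two-pass
  rule.
* Gene-level de-duplication of large-effect counts is reported both
  ways (site-level totals and unique affected genes) because the two
  published figures use inconsistent implicit rules.
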