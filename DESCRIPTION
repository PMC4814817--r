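Package: popsweep
Title: Diversity Scans, Selective-Sweep Detection and CNV Calling for
    Inbred Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of multi-sample
    resequencing panels of highly inbred (selfing) crop species such as
    soybean, structured as wild / landrace / elite groups.  Implements
    site-level quality-control filters for SNP sets, functional-effect
    annotation of SNPs and short indels against GFF3 gene models
    (synonymous/non-synonymous calls, premature-stop, stop-loss,
    start-loss and splice-site categories, frameshift indels, 4-fold
    degenerate site extraction), sliding-window nucleotide diversity
    (theta-pi, Watterson's theta-w, Tajima's D) and Hudson Fst, linkage
    disequilibrium decay in r-squared, the pi-ratio selective-sweep scan
    (diversity ratio between a diverse and a selected group with
    top-quantile window selection and locus merging), read-depth based
    copy-number segmentation, and group-wise summary reporting.  A
    coalescent and Balding-Nichols synthetic-data generator emulates the
    assumed population structure and provides planted-truth panels for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
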