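Package: poolsweeps
Title: Pool-Seq Selection Scans with Permutation Nulls and Chloroplast
    Haplotype Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate selective sweeps from pooled whole-genome
    resequencing of contrasted tree populations (orchard versus wild,
    regional subpopulations). Computes windowed nucleotide diversity and
    Tajima's D from pooled allele counts, tests between-group differences
    with a genome-shuffling permutation null (consecutive-window and
    stringent single-window calling rules, histogram-based local false
    discovery rates), scans 10-gene intervals for major-allele fixation
    outliers, deconvolves pooled chloroplast samples into haplotype
    frequency peaks from binned allele-frequency histograms, and validates
    candidates with per-gene diversity, heterozygosity and Weir-Cockerham
    F_ST from individual genotypes. Includes a calibrated synthetic-data
    generator (finite pools, binomial read sampling, localized sweeps,
    chloroplast haplotype mixtures) with ground-truth labels, plus readers
    and writers for PoPoolation2 sync, samtools pileup, VCF, BED and GFF3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
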