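Package: panhap
Title: Pan-Genome Composition, Variant Effects, and Haplotype-Based
    Breeding Analysis for Crop Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly analysis toolkit for crop pan-genome studies:
    classification of gene families into core, softcore, dispensable and
    private classes from orthogroup presence/absence matrices; rarefaction
    simulation of pan- and core-genome growth with power-law and
    exponential-decay model fitting and plateau detection; a variant
    catalogue engine (quality/depth filtering, strand-aware functional
    effect classification against gene models, per-chromosome, gene-set
    and region summaries); strand-aware structural-variant merging across
    samples; haplotype enumeration with Duncan's multiple range test and
    superior-haplotype calling; and KASP genotype-matrix scoring.  A
    synthetic-data generator produces every input with known ground truth
    so the full pipeline is testable without external data.
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
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
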