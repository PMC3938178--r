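Package: bsmeth
Title: Methylation Maps and SNV Calling from Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates per-cytosine methylation maps (CG, CHG and CHH contexts)
    and calls single-nucleotide variants from coordinate-sorted alignments of
    bisulfite-treated reads. Implements the major error controls needed for
    high-quality methylation profiling: clonal-read deduplication with a
    high-quality seed, 5' end trimming, elimination of reads with putatively
    failed bisulfite conversion, and PHRED-score filtering of base calls. SNVs
    are detected with a strand-aware adaptation of the VarScan strategy
    (relative allele-frequency threshold plus a one-sided Fisher exact test)
    that accounts for the base identities confounded by bisulfite conversion.
    A binomial test assesses whether an observed methylation level could be
    explained by bisulfite conversion failure, given a conversion rate
    estimated from an unmethylated control genome. A bisulfite read simulator
    with known truth (diploid SNVs, methylation states, conversion failures,
    quality-dependent sequencing errors) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
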