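Package: haplotagr
Title: Haplotagging of Long Sequencing Reads Using Phased Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns long sequencing reads (Nanopore, PacBio) to their
    parental haplotype of origin using phased heterozygous single-nucleotide
    variants from a phased VCF. Scoring uses a multinomial likelihood over
    allele matches and mismatches with per-base sequencing error rates,
    computed in log10 space, and reports a log-likelihood ratio per read. An
    optional negative-binomial error model controls the empirical false
    discovery rate by untagging the lowest-scoring reads. Includes utilities
    to repair common VCF spec violations (string phase-set tags, malformed
    genotype fields, mislabeled sample columns), a truth-labeled diploid
    long-read simulator, and an evaluation harness computing incorrect
    haplotagging rate, false-negative rate and precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
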