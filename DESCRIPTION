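Package: mnvscan
Title: Discovery, Annotation and Mutational-Mechanism Analysis of
    Multi-Nucleotide Variants in Phased Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-scale study of multi-nucleotide
    variants (MNVs): scanning phased multi-sample VCFs for in-cis variant
    pairs, evaluating read-based phasing against trio transmission,
    re-annotating codon-level consequences of same-codon variant pairs
    (gained and rescued nonsense, changed missense), classifying the
    mutational origin of each substitution pattern (independent SNVs,
    polymerase-zeta doublet error, polymerase slippage at repeats),
    estimating per-generation MNV mutation rates, and profiling MNV
    density across genomic annotations.  A synthetic-cohort generator
    plants MNVs of known mechanism into simulated phased cohorts so the
    whole pipeline is testable without access to large human callsets.
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
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
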