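Package: survscan
Title: Settler-Versus-Survivor Selective Mortality Scans from RAD-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting genomic signatures of early-life
    selective mortality in marine cohort studies that sample recently settled
    juveniles (settlers) and older juveniles that survived the post-settlement
    period (survivors) at several localities. Starting from a multi-sample VCF
    of RAD-tag SNPs plus per-individual phenotypic and environmental variables
    derived from otolith readings, the package applies a depth, missingness,
    minor-allele-frequency, tag-depth and Hardy-Weinberg filter cascade,
    collapses SNPs into per-tag haplotype loci, computes Weir-Cockerham F_ST
    with permutation significance, PERMANOVA pseudo-F tests and DAPC, runs
    per-locality redundancy analyses with a loading-based outlier rule, calls
    candidate loci with parallel genotype-phenotype associations across all
    localities, tests predictor-category intersections with an exact multi-set
    hypergeometric test, tests settler-versus-survivor allele-frequency
    changes, and characterises candidates by BLAST mapping class, genomic
    region and codon-level amino-acid effect. A synthetic-cohort generator
    with planted selection provides ground truth for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    vcfR,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
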