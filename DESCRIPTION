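Package: sexscan
Title: Detection and Characterization of Young Homomorphic Sex-Linked Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and delineating young, homomorphic
    sex-linked regions from sex-labeled population resequencing data.
    Implements per-site and windowed differentiation statistics (Weir-Cockerham
    F_ST between the sexes, F_IS, sex-specific heterozygous-site densities),
    exact-test genome-wide sex association with Bonferroni control,
    heterogamety inference, sex-reversal detection and exclusion,
    change-point delineation of pseudoautosomal/sex-linked boundaries,
    Nei-Gojobori (1986) X-Y coding divergence, RAD-seq presence/absence
    sex-marker association, read-pair inversion genotyping, and
    expression-side tests (TPM, quantile normalization, the tau
    tissue-specificity index, tissue-bias calls, chromosomal enrichment).
    A coalescent-free simulator generates diploid populations with a planted
    sex-linked region, sex reversals, X-Y exchange and depth tracks, plus
    expression and RAD-marker matrices, with machine-readable truth files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    SummarizedExperiment,
    jsonlite,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
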