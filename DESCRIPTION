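Package: slafbsa
Title: SLAF-Seq Bulked Segregant Analysis with SNP-Index Genome Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reduced-representation bulked segregant analysis of
    quantitative traits in outcrossing F1 populations. Predicts
    specific-length amplified fragment (SLAF) tags by in-silico double
    restriction digestion of a reference genome with fragment size selection,
    computes fiber-content phenotypes and extreme bulks, applies a staged
    hard-filter cascade to pooled variant calls with conservation accounting,
    scans bulks with the SNP-index and delta SNP-index statistics under a
    10-SNP sliding window with permutation-derived significance thresholds,
    calls and annotates candidate regions against gene models, and
    forward-simulates complete F1 bulked-segregant experiments so that every
    stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
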