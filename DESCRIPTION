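Package: poolscreen
Title: Pooled shRNA Dropout Screen Analysis and Genotype-Stratified Hit Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled short-hairpin RNA dropout screens across cell
    line panels: barcode counting from raw reads, median-of-ratios
    normalization, negative-binomial exact testing of hairpin depletion
    between timepoints, RIGER-style second-best gene ranking and
    multi-criterion lethal-hit calling, genotype-stratified association of
    hits across a cohort (specificity scores and Fisher exact tests),
    single-dose drug-sensitivity classification, two-group sample-size
    calculation, qPCR delta-delta-Ct and ChIP percent-input quantification,
    and strand-aware average signal profiles around transcription start
    sites. Includes a negative-binomial screen simulator with planted
    common and genotype-specific lethal genes so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    MASS,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
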