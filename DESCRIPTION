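Package: vcbench
Title: Closed-Loop Benchmarking of SNV Callers Against Dual Truth Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a neutral diploid population with a rescaled
    Wright-Fisher forward model, derives the segregating-SNV truth set (P),
    injects divergence into the reference genome to create a second truth
    set (D), generates paired-end short reads, emulates a variant caller
    with configurable error behaviour and annotation-score distributions,
    and evaluates any VCF against the dual truth set: recovery rate,
    false-positive proportion, F score, QUAL and GATK-style hard filters,
    repeat-class stratification of false positives, Fisher enrichment
    tests, mapping-quality and quality-by-depth diagnostics, and
    Spearman trends against reference divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
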