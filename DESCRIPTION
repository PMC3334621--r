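Package: isomirseq
Title: IsomiR Detection, Nomenclature and Quantification from Small-RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A small-RNA sequencing analysis toolkit that aligns short tags to
    pre-miRNA hairpin references using two complementary strategies (recursive
    length trimming and adaptor-trimmed exact-end alignment with
    substitution-only placement), classifies sequence variants of mature
    miRNAs (isomiRs) into seven mutually exclusive categories, renders and
    parses a machine-readable isomiR nomenclature, quantifies expression as
    tags per million corrected by trimmed-mean-of-M-values effective library
    sizes with a decoy-derived noise floor, and runs downstream cohort
    analyses: arm-dominance and arm-switching detection, screening for
    AGO2-cleaved pre-miRNA (ac-pre-miRNA) candidate hairpins, and
    paired-condition ablation testing with depth resampling and chi-square
    statistics. A seeded synthetic-data generator produces hairpins,
    annotations and multi-sample read cohorts with full ground truth so the
    entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    edgeR,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
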