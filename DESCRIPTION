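Package: cleavekit
Title: Degradome-Guided Identification of miRNA Cleavage Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated small-RNA / degradome / transcriptome pipeline for
    validating plant miRNA cleavage targets and linking them to differential
    expression between conditions. Provides small-RNA tag profiling (length
    distribution, first-base preference), antiparallel miRNA-transcript duplex
    scanning with plant-convention penalty scoring and a retention ceiling,
    degradome 5'-signature mapping with five-category cleavage-site
    classification and t-plot tables, a documented median-of-ratios plus
    Welch-test differential-expression method, an integration step that
    joins differentially expressed miRNAs with cleavage-validated targets into
    a pair report, and seeded synthetic-data generators with planted ground
    truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
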