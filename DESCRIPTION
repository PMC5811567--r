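Package: bulbmiR
Title: Small RNA miRNA Discovery, Target Scoring and Degradome Validation for
    Bulb Plants
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of a plant small-RNA miRNA discovery
    pipeline: adapter trimming and 18-30 nt length filtering, ncRNA
    (rRNA/tRNA/snRNA/snoRNA) removal, homology-based conserved miRNA
    identification with stem-loop hairpin validation, rule-based novel miRNA
    calling from transcript-anchored read stacks, MFE/AMFE/MFEI precursor
    statistics under a simplified nearest-neighbour energy model,
    position-weighted plant miRNA target scoring, degradome (PARE) cleavage-site
    detection with the five-category T-plot classification, and stem-loop qPCR
    relative quantification via 2^-ddCt. Ships a ground-truthed synthetic data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, Transcriptomics
RoxygenNote: 7.3.3
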