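Package: duonscan
Title: REDACT Scoring of Potential Duon Mutations in Cancer Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects potential duon mutations - recurrent somatic coding
    variants with evidence of dual protein-level and regulatory effects - in
    multi-omic tumor cohorts. Implements the six-layer REDACT evidence score
    (Recurrence, mRNA Expression change, DNase hypersensitivity overlap,
    Allelic expression imbalance, ChIP peak overlap, Transcription-factor
    motif perturbation), within-gene permutation null models for regulatory
    overlap, Fisher and Hartung combined p-values with Benjamini-Hochberg
    correction, and downstream splicing-entropy and target-concordance
    analyses. Ships a fully seeded synthetic multi-omic cohort generator
    with planted ground-truth duon mutations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
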