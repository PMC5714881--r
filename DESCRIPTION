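Package: patchlink
Title: Quality Control and Differential Expression for Patch-Seq Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for patch-seq experiments, in which RNA of
    individually patch-clamped neurons is harvested for CEL-seq style
    single-cell RNA sequencing after in vivo labeling or functional imaging.
    Implements UMI-based quantification and tpm normalization, ERCC spike-in
    detection-efficiency estimation and technical-noise fitting with
    variable-gene calling, two contamination estimators (cross-species barcode
    contamination via shared k-mer genome masking with an exact-match read
    mapper, and marker-based tissue contamination from GABAergic and
    glutamatergic marker transcripts), a sigma-score differential-expression
    statistic with a proportional label-shuffle significance test, and
    classification of visually evoked calcium responses into high- and
    low-speed tuned cells. A synthetic-data generator with recorded ground
    truth emulates every input so each estimator can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
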