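Package: multioptosis
Title: Pan-Cancer Multi-Omic Regulated Cell Death Signature Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers mono-omic, multi-phenotypic signatures of regulated
    cell death (RCD) genes across cancer cohorts. Seven omic layers (protein,
    mutation, copy number, miRNA, transcript isoform, mRNA, CpG methylation)
    are screened against tumor mutation burden, microsatellite instability and
    tumor stemness by rank correlation under genome-wide Holm-Bonferroni
    control; significant features are coded for tumor-versus-normal polarity,
    Cox hazard and Kaplan-Meier survival contexture over four endpoints,
    tumor-microenvironment and immune hot/cold contexture, grouped into
    signatures, encoded in an eleven-component identifier, ranked for clinical
    meaningfulness and validated against an independent meta-Z table. A
    synthetic pan-cancer generator with planted effects makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Software, GeneExpression, Survival, Transcriptomics, CopyNumberVariation
RoxygenNote: 7.3.3
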