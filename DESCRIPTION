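Package: stipr
Title: Functional Stratification of Tumor Cell Lines from Label-Free Growth Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumor cell line responses to non-cytotoxic
    immunomodulatory formulations from label-free confluence time courses.
    Implements the STIP framework: per-group kinetic metrics (divergence onset,
    sustained duration, log-phase slope, AUC, intra-assay CV), a three-class
    stimulatory/inhibitory/neutral decision tree with a cytotoxicity gate and
    secretome congruence (IFN-gamma/IL-10 ratio), a z-score-weighted Functional
    Stratification Index (FSI) ranking, intra-assay and interbatch QC verdicts,
    line-by-formulation compatibility matrices, Ward-D2 phenotype clustering,
    and a seeded synthetic plate simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    cluster,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
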