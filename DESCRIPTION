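Package: dompep
Title: Domain-Peptide Interaction Prediction for Modular Binding Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions mediated by modular
    peptide-binding domains (PDZ and SH2 families) from domain-peptide
    array data and domain sequences. Implements pairwise specificity
    metrics (ligand-binding similarity, position weight matrix distance,
    domain sequence identity), LBS-calibrated thresholding and grouping of
    specificity-similar domains, linear support-vector-machine binding
    models with leave-one-out model selection over iteratively pooled
    training sets, proteome scanning with Z-score standardization and
    stringency calls, and ROC-based evaluation including a bundled
    Scrib PDZ validation panel. A seeded synthetic-data generator with
    planted specificity groups makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
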