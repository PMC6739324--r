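Package: dna6ma
Title: Cross-Species Prediction of DNA N6-Methyladenine Sites from Sequence Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA N6-methyladenine (6mA) modification sites from
    fixed-length nucleotide windows centred on a candidate adenine. Implements
    five sequence feature encodings (k-mer composition, k-spaced nucleotide
    pair frequencies, nucleic shift density, three-bit binary code, and PWM
    motif log-odds scores parsed from MEME minimal motif format), classifier
    training and evaluation (extremely randomised trees, random forest,
    gradient boosting, AdaBoost, RBF support vector machine) under stratified
    k-fold cross-validation, jackknife and independent-test protocols with
    Sn/Sp/ACC/MCC/AUC/AP/F1 measures, a synthetic planted-motif benchmark
    generator, and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
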