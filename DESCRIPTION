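Package: lumipred
Title: Sequence-Based Prediction of Bioluminescent Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bioluminescent proteins (BLPs) from amino-acid sequence
    alone. Implements four sequence-derived feature encoders (amino-acid
    composition, dipeptide composition, gapped sequence motifs, and
    physicochemical-property averages), an entropy-based gapped motif
    discovery algorithm that ranks candidate patterns by the difference of
    two class-conditional information gains (DIG), a filter-plus-wrapper
    feature-selection procedure (Fisher-Markov-style ranking followed by
    sequential backward selection), RBF-kernel support vector machine
    classifiers tuned by grid search, and a lineage-specific model scheme
    that dispatches queries to bacteria-, eukaryota- or archaea-specific
    classifiers with a universal fallback. Includes the full evaluation
    protocol (sensitivity, specificity, accuracy, Matthews correlation,
    ROC/AUC, stratified cross-validation, repeated balanced under-sampling,
    and a Shapiro-Wilk-gated paired significance test) and a seeded
    synthetic-sequence generator with planted motifs and compositional bias
    so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
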