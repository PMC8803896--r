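Package: protscreen
Title: Sequence-Based Protein Classification and Virtual Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for binary classification of proteins from primary
    sequence alone, aimed at recognising functional classes such as
    antioxidant proteins and at virtual screening of candidate enzymes.
    Implements the 188-dimensional composition/physicochemical descriptor
    (amino-acid composition plus composition-transition-distribution
    features over eight residue groupings), the composition of k-spaced
    amino-acid pairs (CKSAAP), Max-Relevance-Max-Distance (MRMD) feature
    ranking with accuracy-driven subset selection, random undersampling
    for class rebalancing, and a random-forest classifier with a full
    evaluation suite (sensitivity, specificity, accuracy, Matthews
    correlation, ROC AUC). A synthetic-sequence generator with a planted
    compositional signal makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
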