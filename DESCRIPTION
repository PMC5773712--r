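Package: sigscan
Title: Signal Peptide Classification and Cleavage-Site Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies protein sequences as secretory or non-secretory and
    locates signal-peptide cleavage sites. Sequences are encoded into a
    220-element feature vector combining residue occurrence, position-gap
    weighted adjacency-pair statistics over three physicochemical scales
    (hydrophobicity, hydrophilicity, side-chain mass), and composition and
    position summaries. Classification uses a 220-50-2 feed-forward network
    trained by full-batch backpropagation with an adaptive learning rate.
    Cleavage sites are found with a log-ratio position weight matrix
    constrained by the von Heijne style (-3,-1) residue rules. Includes
    evaluation statistics (sensitivity, specificity, accuracy, Matthews
    correlation, ROC/AUC), self-consistency, k-fold cross-validation and
    jackknife protocols, FASTA and annotation-table input with curation
    filters, and a seeded synthetic-sequence generator with planted
    cleavage sites.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
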