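Package: lipidtraffic
Title: Presence-Based Lipid Traffic Analysis over Compartment Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Systemic analysis of lipidomics data across metabolically
    connected compartments. Parses shorthand lipid nomenclature, calls
    per-group presence from signal occupancy, classifies the spatial
    distribution of every lipid variable over a compartment network
    (ubiquitous A-type, isolated U-type, adjacent-pair B-type and
    non-adjacent-pair N2-type), and compares phenotypes with
    Jaccard-Tanimoto coefficients and exact hypergeometric p-values.
    Quantitative stages provide error-normalized fold changes,
    coefficient-of-variation summaries, fatty-acid mol% composition
    tables with propagated errors, and a balanced-split random-forest
    sex classifier with optional BMI correction. Includes seeded
    synthetic-data generators so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
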