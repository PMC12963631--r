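Package: scfvforge
Title: Charge-Based Design, Prediction and Ranking of scFv Intrabodies
Version: 0.1.0
Authors@R: person("scfvforge", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for reformatting antibodies as single-chain variable
    fragment (scFv) intrabodies. Implements Chothia template-transfer
    numbering and CDR/framework segmentation of variable domains,
    counting-charge physicochemical profiling (net charge, charge at pH
    5.5, isoelectric point, GRAVY, aliphatic mole percent), a linear
    charge-to-solubility predictor for cytoplasmic expression, charged
    interdomain linker and epitope-tag libraries with construct assembly
    and charge budgeting, fixed-position masks plus validation, ranking
    and ensemble analysis of inverse-folding outputs, repertoire-scale
    filtering and deduplication, and seeded synthetic-data generators so
    every analysis is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
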