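Package: rpibind
Title: Three-Step Structure-Based Prediction of RNA-Protein Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts RNA-protein interfaces in three cascaded steps: RNA-binding
    residues on proteins, protein-binding nucleotides on RNAs, and
    residue-nucleotide contacts at the interface. Protein backbones are encoded
    with the 16-letter protein-block structural alphabet and RNA secondary
    structure with a 12-class local-conformation alphabet; interface statistics
    (compositions, log-odds preferences, mutual interaction propensity matrices)
    feed windowed feature vectors classified by random forests. Includes
    structure readers, a contact extractor, a seed-reproducible synthetic
    complex generator with planted interface enrichments, grouped
    cross-validation, and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    nnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
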