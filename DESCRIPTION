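Package: phosloc
Title: Deep-Learning-Feature-Assisted Phosphosite Localization and PSM Rescoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phosphosite localization and peptide-spectrum-match (PSM)
    rescoring for shotgun phosphoproteomics, using retention-time and
    fragment-ion-intensity predictions from any external predictor that
    conforms to a simple tab-separated interface. Implements six
    spectrum-similarity scores (including spectral entropy similarity),
    retention-time difference scores, a binomial site-localization score,
    score combination with base-10 softmax site probabilities,
    semi-supervised SVM rescoring with target-decoy q-values, false
    localization rate evaluation against ground-truth libraries,
    phosphosite-level quantification via 15-mer flanking identifiers, and a
    fully seeded synthetic phosphoproteomics data generator with a mock
    predictor so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
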