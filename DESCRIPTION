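Package: stromasig
Title: Stromal Confounding of EMT and Stemness Expression Signature Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much EMT, mesenchymal and stemness gene-signature
    scores in bulk tumor expression data are driven by stromal (chiefly
    fibroblast) content rather than cancer-cell-intrinsic state. Provides
    coherence-scored signature scoring for bulk samples and single cells,
    TMM/TPM preprocessing, score-purity association tests with multiplicity
    correction, cell-type mixing (pseudobulk) simulation with known ground
    truth, single-cell marker attribution of signature genes to cell types,
    and derivation of proxy gene sets for classifier-defined subtypes, all
    exercised end-to-end on seeded synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
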