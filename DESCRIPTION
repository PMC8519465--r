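Package: cellstate
Title: Cross-Cell-Type Prediction of Transcriptional Drug Response
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the transcriptional response to a drug in one cell type
    from the measured response in another, using a denoising autoencoder with a
    shared encoder and cell-type-specific decoders trained on landmark-gene
    perturbation signatures. Includes profile ingestion and normalization for
    GCT/TSV signature matrices, the three-stage training protocol with early
    stopping and transfer-learning fine-tuning, drug-holdout and
    drug-family-holdout cross-validation with baseline fold-change reporting,
    model interpretation tools (latent-space alignment, transcription-factor
    target inference by gradient ascent on the input, masked-subset decoder
    gene importance, binomial enrichment), and a synthetic paired-cohort
    generator with known shared-latent structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
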