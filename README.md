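# cellstate

Predicts the transcriptional response to a drug in one cell type from the
measured response in another. The cost of profiling every drug in every cell
line grows combinatorially; `cellstate` trains a translation model on the
(drug × cell type) response blocks that *have* been measured — e.g. L1000
landmark-gene signatures, z-score-like vectors over 978 genes — and predicts
the missing combinations, for computational biologists working with
perturbation compendia or small external response panels.

## The model

A denoising autoencoder with a **shared encoder** and **cell-type-specific
decoders**. For a response profile *x* ∈ [−1, 1]^G:

    enc:  dropout(x) → dense(512, LReLU) → dense(256, LReLU) → z ∈ R^128  (L1 on z)
    dec_c: z → dense(256, LReLU) → dense(512, LReLU)
           → tanh( dense( [hidden ‖ dropout(x)] ) )        (skip connection)

The encoder learns a cell-neutral representation of the drug effect; each
decoder renders it in its own cell type. Prediction for target cell *c* from
a profile measured in any cell type is `dec_c(enc(x), x)`. Training is
staged: (1) joint denoising autoencoder over all cell types, (2) per-cell
decoders (copied from the shared decoder) trained round-robin with the
encoder on all (input cell → target cell) drug pairs, (3) encoder frozen,
decoders polished — each stage with drug-level validation early stopping
(patience 5, Adam, MSE loss).

Accuracy is reported per drug as the Pearson correlation (PCC) of the
prediction with the observed target response, against the naive baseline
that the target cell responds exactly like the input cell; their ratio is
the fold-change over baseline. Model analysis tools: latent-space alignment
matrices, transcription-factor target inference by gradient ascent on the
input, exact binomial enrichment, and masked-subset decoder gene importance.
A synthetic cohort generator with known shared-latent structure makes the
whole pipeline testable offline.

## Worked example

```r
library(cellstate)

res   <- generate_cohort(seed = 1)     # 300 drugs × {cellA, cellB} × 200 genes
train <- cellstate:::paired_subset(res$paired, res$paired$drugs[1:270])
test  <- cellstate:::paired_subset(res$paired, res$paired$drugs[271:300])

config <- model_config(input_dim = 200, encoder_widths = c(128L, 64L),
                       latent_dim = 32L, learning_rate = 1e-3, max_epochs = 60L)
model  <- train_full_model(train, config, seed = 1)     # ~8 s on one CPU

evaluate_predictions(model, test, input_cells = "cellA", target_cell = "cellB")
#> EvalReport: 30 rows | mean PCC pred 0.580 vs baseline 0.241
#> | mean fold-change 2.84 (30 defined) | paired p = 7.14e-22

latent_alignment(model, test, "cellA", "cellB")
#> LatentAlignmentMatrix: 30 drugs | latent diag mean 0.736,
#> off-diag mean 0.489 | input diag mean 0.241
```

Reading: on 30 drugs never seen in training, the model's predictions
correlate 0.58 with the observed target-cell responses, versus 0.24 for the
copy-the-other-cell baseline — a 2.8-fold improvement, and the same drug's
latent codes in the two cell types correlate far more strongly (diagonal
0.74) than its raw profiles do (0.24): the encoder has captured the drug
effect in a cell-neutral way.

Real data enters through `read_matrix` (GCT 1.3 / TSV + annotation sidecar),
`average_condition_replicates`, `normalize_global` and `build_paired_set`;
external expression sets through `cage_counts_to_profiles` / `logfc_profile`
and `rescale_to_model`; small external panels can refine a trained model via
`transfer_finetune` (leave-one-drug-out). `crossval_by_drug` and
`holdout_families` run the drug- and drug-family-holdout protocols. A small
CLI wraps the pipeline: `Rscript -e 'cellstate::dcs()' simulate|ingest|train|predict|cv ...`.

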