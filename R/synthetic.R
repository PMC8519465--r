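#' Generate a synthetic paired perturbation cohort
#'
#' Builds a complete drug x cell-type block with a known shared-latent
#' structure. Every drug carries a k-dimensional effect code shared exactly
#' across cell types; each cell type reads the code out through its own dense
#' mixing map squashed by tanh. Cell maps share a common component
#' (\code{map_overlap}) so that the same drug produces positively correlated
#' profiles across cell types — mirroring real cross-cell responses, where
#' the naive same-as-other-cell baseline is clearly better than chance — and
#' the cross-cell input correlation grows with \code{shared_fraction}. On top
#' of the shared readout, each profile has a cell-and-drug-specific component
#' (weight \code{1 - shared_fraction}) that no model can predict from another
#' cell type, plus per-gene Gaussian noise. The block is normalized to
#' [-1, 1] by its global maximum, like real training data.
#'
#' The generative truth (codes, maps, noise, planted sets) is returned so
#' recovery tests can check what a trained model should find.
#'
#' @param n_drugs number of drugs (default 300).
#' @param cell_types cell-type identifiers (default two).
#' @param n_genes gene-space size (default 200).
#' @param k true latent dimensionality of the drug effect (default 16).
#' @param shared_fraction weight of the shared readout in [0, 1] (default 0.6).
#' @param noise_sd per-gene additive noise scale (default 0.3).
#' @param seed integer seed; the cohort is a pure function of it.
#' @param map_overlap fraction of cell-map variance shared between cell types
#'   (default 0.5).
#' @param importance_genes optional gene subset; when given, all mixing maps
#'   load on these genes only, so the signal (and everything a decoder can
#'   use) lives in a known planted set while the remaining genes are pure
#'   noise.
#' @return list with \code{paired} (a normalized \code{PairedSet}) and
#'   \code{truth} (a \code{SyntheticTruth}).
#' @export
generate_cohort <- function(n_drugs = 300L, cell_types = c("cellA", "cellB"),
                            n_genes = 200L, k = 16L, shared_fraction = 0.6,
                            noise_sd = 0.3, seed = 1L, map_overlap = 0.5,
                            importance_genes = NULL) {
  .assert(k < n_genes, "true latent size k must be below n_genes")
  .assert(shared_fraction >= 0 && shared_fraction <= 1,
          "shared_fraction must be in [0, 1]")
  .assert(map_overlap >= 0 && map_overlap <= 1, "map_overlap must be in [0, 1]")
  .assert(noise_sd >= 0, "noise_sd must be nonnegative")
  .assert(length(cell_types) >= 2, "need at least two cell types")
  genes <- sprintf("g%04d", seq_len(n_genes))
  drugs <- sprintf("drug%04d", seq_len(n_drugs))
  if (!is.null(importance_genes))
    .assert(all(importance_genes %in% genes), "importance_genes outside gene space")
  truth <- .with_seed(seed, {
    Z <- matrix(stats::rnorm(n_drugs * k), n_drugs, k, dimnames = list(drugs, NULL))
    # map entries scaled so that (map %*% code) is ~N(0, 1) per gene
    rmap <- function() matrix(stats::rnorm(k * n_genes, sd = 1 / sqrt(k)),
                              k, n_genes, dimnames = list(NULL, genes))
    M0 <- rmap()
    cell_maps <- lapply(cell_types, function(ct)
      sqrt(map_overlap) * M0 + sqrt(1 - map_overlap) * rmap())
    names(cell_maps) <- cell_types
    private_codes <- lapply(cell_types, function(ct)
      matrix(stats::rnorm(n_drugs * k), n_drugs, k, dimnames = list(drugs, NULL)))
    names(private_codes) <- cell_types
    private_maps <- lapply(cell_types, function(ct) rmap())
    names(private_maps) <- cell_types
    noise <- lapply(cell_types, function(ct)
      matrix(stats::rnorm(n_genes * n_drugs, sd = noise_sd), n_genes, n_drugs,
             dimnames = list(genes, drugs)))
    names(noise) <- cell_types
    if (!is.null(importance_genes)) {
      zero_out <- !(genes %in% importance_genes)
      for (ct in cell_types) {
        cell_maps[[ct]][, zero_out] <- 0
        private_maps[[ct]][, zero_out] <- 0
      }
    }
    structure(list(latent_factors = Z, cell_maps = cell_maps,
                   private_codes = private_codes, private_maps = private_maps,
                   noise = noise, shared_fraction = shared_fraction,
                   noise_sd = noise_sd, map_overlap = map_overlap,
                   planted_tf_sets = list(),
                   planted_importance_genes = importance_genes,
                   genes = genes, drugs = drugs, cell_types = cell_types,
                   seed = as.integer(seed)),
              class = "SyntheticTruth")
  })
  list(paired = synthesize_cohort(truth), truth = truth)
}

#' Materialize the paired block of a synthetic truth
#'
#' Pure arithmetic (all randomness lives in the truth object), so editing the
#' truth — e.g. planting a factor-target structure — and re-synthesizing
#' changes exactly the columns the edit touches.
#'
#' @param truth a \code{SyntheticTruth}.
#' @return a normalized \code{PairedSet}.
#' @export
synthesize_cohort <- function(truth) {
  .assert(inherits(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  s <- truth$shared_fraction
  mats <- lapply(truth$cell_types, function(ct) {
    shared <- t(tanh(truth$latent_factors %*% truth$cell_maps[[ct]]))
    private <- t(tanh(truth$private_codes[[ct]] %*% truth$private_maps[[ct]]))
    m <- s * shared + (1 - s) * private + truth$noise[[ct]]
    dimnames(m) <- list(truth$genes, truth$drugs)
    m
  })
  names(mats) <- truth$cell_types
  .assert(all(vapply(mats, function(m) all(is.finite(m)), logical(1))),
          "generator produced non-finite values")
  scale <- max(vapply(mats, function(m) max(abs(m)), numeric(1)))
  .assert(scale > 0, "degenerate all-zero cohort")
  mats <- lapply(mats, function(m) m / scale)
  structure(list(genes = truth$genes, cell_types = truth$cell_types,
                 drugs = truth$drugs, mats = mats, normalization_scale = scale),
            class = "PairedSet")
}

#' Plant a factor -> target-gene structure into a synthetic truth
#'
#' Rewires one latent factor so that, in every cell map, it loads only on the
#' chosen regulator gene and its target set, with loading magnitude at least
#' five times the background loading RMS. After re-synthesizing, those genes
#' co-vary strongly through the planted factor, giving the input-optimization
#' target inference a known ground truth to recover.
#'
#' @param truth a \code{SyntheticTruth}.
#' @param factor index of the latent factor to rewire.
#' @param tf_gene the regulator gene.
#' @param target_genes character vector of target genes.
#' @param strength loading magnitude as a multiple of the background RMS
#'   (default 5).
#' @return the edited \code{SyntheticTruth} with the planted set recorded in
#'   \code{planted_tf_sets}.
#' @export
plant_tf_structure <- function(truth, factor, tf_gene, target_genes, strength = 5) {
  .assert(inherits(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  k <- ncol(truth$latent_factors)
  .assert(factor >= 1 && factor <= k, "factor index %d out of range 1..%d", factor, k)
  planted <- union(tf_gene, target_genes)
  .assert(all(planted %in% truth$genes), "planted genes outside the gene space")
  .assert(strength >= 5, "planted loadings must be at least 5x background")
  background_rms <- sqrt(mean(unlist(lapply(truth$cell_maps, function(m) m^2))))
  idx <- match(planted, truth$genes)
  # Deterministic regulon pattern: magnitudes ramp over [strength, 2*strength]
  # x background RMS and every third target is repressed (negative loading),
  # the regulator itself always activated. A constant one-sign loading would
  # saturate the tanh readout into a rank-1 flat block with no gene-to-gene
  # variation, which carries no recoverable gene-wise signature; a mixed-sign,
  # mixed-strength regulon is also what TF modules look like in real data.
  mags <- seq(strength, 2 * strength, length.out = length(idx)) * background_rms
  signs <- rep_len(c(1, 1, -1), length(idx))
  signs[1] <- 1  # union() puts tf_gene first
  for (ct in truth$cell_types) {
    truth$cell_maps[[ct]][factor, ] <- 0
    truth$cell_maps[[ct]][factor, idx] <- signs * mags
  }
  truth$planted_tf_sets[[as.character(factor)]] <-
    list(tf = tf_gene, targets = setdiff(planted, tf_gene))
  truth
}

#' Write a synthetic cohort in the real-data exchange format
#'
#' Emits the TSV matrix plus metadata sidecar consumed by
#' \code{\link{read_matrix}}, so the whole ingest -> train -> evaluate path
#' can be exercised on synthetic data unchanged.
#'
#' @param paired a \code{PairedSet}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(paired, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  values <- do.call(cbind, lapply(paired$cell_types, function(ct) {
    m <- paired$mats[[ct]]
    colnames(m) <- paste(paired$drugs, ct, sep = "_")
    m
  }))
  meta <- do.call(rbind, lapply(paired$cell_types, function(ct)
    data.frame(sample_id = paste(paired$drugs, ct, sep = "_"),
               pert_id = paired$drugs, cell_id = ct, pert_type = "compound",
               pert_time = "averaged", pert_dose = "averaged",
               stringsAsFactors = FALSE)))
  ps <- profile_set(values, paired$genes, meta, paired$normalization_scale)
  write_profile_set_tsv(ps, file.path(dir, "profiles.tsv"),
                        file.path(dir, "meta.tsv"))
  invisible(dir)
}
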