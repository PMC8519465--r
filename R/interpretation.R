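#' Latent-space alignment matrix between two cell types
#'
#' Correlates the latent codes of every drug in cell A with every drug in
#' cell B, alongside the same-shape correlations of the raw input profiles.
#' A trained model that captures the drug effect in a cell-neutral way shows
#' a strong diagonal in the latent matrix even where the input-space
#' correlation is weak. Rows and columns are sorted by descending input-space
#' diagonal correlation.
#'
#' @param model a trained \code{cs_model}.
#' @param paired_test a \code{PairedSet} of (ideally held-out) drugs
#'   containing both cell types.
#' @param cellA,cellB cell-type identifiers.
#' @return an object of class \code{LatentAlignmentMatrix} with fields
#'   \code{drugs}, \code{matrix} (latent-space PCCs) and \code{input_matrix}.
#' @export
latent_alignment <- function(model, paired_test, cellA, cellB) {
  .assert(all(c(cellA, cellB) %in% paired_test$cell_types),
          "both cell types must be present in the test set")
  XA <- t(paired_test$mats[[cellA]])
  XB <- t(paired_test$mats[[cellB]])
  ZA <- encode(model, XA)
  ZB <- encode(model, XB)
  .assert(all(apply(ZA, 1, stats::sd) > 0) && all(apply(ZB, 1, stats::sd) > 0),
          "constant latent code: correlation undefined")
  M <- stats::cor(t(ZA), t(ZB))
  IM <- stats::cor(t(XA), t(XB))
  ord <- order(diag(IM), decreasing = TRUE)
  drugs <- paired_test$drugs[ord]
  M <- M[ord, ord, drop = FALSE]
  IM <- IM[ord, ord, drop = FALSE]
  dimnames(M) <- dimnames(IM) <- list(drugs, drugs)
  structure(list(drugs = drugs, matrix = M, input_matrix = IM),
            class = "LatentAlignmentMatrix")
}

#' @export
print.LatentAlignmentMatrix <- function(x, ...) {
  d <- diag(x$matrix)
  off <- x$matrix[row(x$matrix) != col(x$matrix)]
  cat(sprintf(paste0("LatentAlignmentMatrix: %d drugs | latent diag mean %.3f,",
                     " off-diag mean %.3f | input diag mean %.3f\n"),
              length(x$drugs), mean(d), mean(off), mean(diag(x$input_matrix))))
  invisible(x)
}

# objective and input gradient for maximizing one output gene of one decoder
.tf_objective <- function(model, x, tf_idx, target_cell) {
  X <- matrix(x, nrow = 1)
  alpha <- model$config$leaky_alpha
  fe <- .enc_forward(model$encoder, X, alpha)
  dec <- model$decoders[[target_cell]]
  fd <- .dec_forward(dec, fe$z, X, alpha)
  dY <- matrix(0, 1, length(x))
  dY[1, tf_idx] <- 1
  g <- .net_backward(model$encoder, dec, X, fe, fd, dY, alpha,
                     want_input_grad = TRUE)
  list(value = fd$Y[1, tf_idx], grad = drop(g$dX))
}

#' Infer transcription-factor targets by input optimization
#'
#' Starting from a small seeded random profile, performs gradient ascent on
#' the chosen gene's value in the target-cell decoder output (model weights
#' frozen), clipping the input to [-1, 1] after every step. Steps that would
#' decrease the objective are rejected and the step size halved, so the
#' objective is non-decreasing over accepted steps. The genes with the
#' highest values in the optimized input profile — the co-activated inputs
#' the model uses to drive the factor up — are reported as its predicted
#' targets, excluding the factor itself.
#'
#' @param model a trained \code{cs_model}.
#' @param tf gene identifier present in the model's gene space.
#' @param target_cell decoder in which the gene's output is maximized.
#' @param n_targets number of targets to report (default 50).
#' @param steps maximum optimization steps (default 500).
#' @param step_size initial gradient-ascent step (default 0.1, halved on
#'   rejected steps).
#' @param init_scale half-width of the uniform random initialization.
#' @param seed seed for the initialization.
#' @return an object of class \code{TFTargetPrediction} with fields
#'   \code{tf}, \code{optimized_profile}, \code{predicted_targets} and
#'   \code{objective}.
#' @export
predict_tf_targets <- function(model, tf, target_cell, n_targets = 50L,
                               steps = 500L, step_size = 0.1, init_scale = 0.1,
                               seed = 1L) {
  tf_idx <- match(tf, model$gene_space)
  .assert(!is.na(tf_idx), "gene '%s' is not in the model's gene space", tf)
  .assert(target_cell %in% names(model$decoders),
          "no decoder for cell type '%s'", target_cell)
  G <- model$config$input_dim
  x <- .with_seed(seed, stats::runif(G, -init_scale, init_scale))
  ob <- .tf_objective(model, x, tf_idx, target_cell)
  .assert(all(is.finite(ob$grad)), "non-finite gradient at initialization")
  step <- step_size
  for (i in seq_len(steps)) {
    if (!all(is.finite(ob$grad)))
      .stopf("non-finite gradient at step %d (objective %.4g)", i, ob$value)
    cand <- pmin(pmax(x + step * ob$grad, -1), 1)
    ob2 <- .tf_objective(model, cand, tf_idx, target_cell)
    if (ob2$value >= ob$value) {
      x <- cand
      ob <- ob2
    } else {
      step <- step / 2
      if (step < 1e-6) break
    }
  }
  ord <- order(x, decreasing = TRUE)
  ord <- ord[ord != tf_idx]
  targets <- model$gene_space[ord[seq_len(min(n_targets, length(ord)))]]
  structure(list(tf = tf,
                 optimized_profile = profile(x, model$gene_space,
                                             pert_id = paste0("optimized_", tf),
                                             cell_id = target_cell),
                 predicted_targets = targets, objective = ob$value),
            class = "TFTargetPrediction")
}

#' Filter transcription factors and pick their top reference targets
#'
#' Keeps only factors that are upregulated in at least one treatment profile
#' (maximum value above \code{upreg_min}) and that have at least
#' \code{min_targets} reference targets at or above the binding-score
#' threshold; survivors are mapped to their top \code{min_targets} targets by
#' score (ties broken by input order).
#'
#' @param tf_targets named list: per factor, a data.frame with columns
#'   \code{target} and \code{score}.
#' @param profiles a \code{ProfileSet} of treatment responses over the gene
#'   space (used for the upregulation criterion).
#' @param min_targets minimum (and reported) number of targets (default 50).
#' @param score_min binding-score threshold (default 100).
#' @param upreg_min upregulation threshold on the normalized profile values
#'   (default 0.5).
#' @return named list factor -> character vector of top targets.
#' @export
filter_tfs <- function(tf_targets, profiles, min_targets = 50L, score_min = 100,
                       upreg_min = 0.5) {
  out <- list()
  for (tf in names(tf_targets)) {
    row <- match(tf, profiles$genes)
    if (is.na(row)) next
    if (max(profiles$values[row, ]) <= upreg_min) next
    tab <- tf_targets[[tf]]
    tab <- tab[tab$score >= score_min, , drop = FALSE]
    if (nrow(tab) < min_targets) next
    tab <- tab[order(-tab$score), , drop = FALSE]
    out[[tf]] <- as.character(tab$target[seq_len(min_targets)])
  }
  out
}

#' Binomial enrichment of a predicted gene set in a reference set
#'
#' The expected overlap under independence is
#' \code{|predicted| * |reference| / universe_size}; fold enrichment is the
#' observed overlap over that expectation, and the p-value is the exact
#' upper-tail binomial probability of at least the observed overlap in
#' \code{|predicted|} draws with success probability
#' \code{|reference| / universe_size}.
#'
#' @param predicted,reference gene sets (character vectors, subsets of the
#'   universe).
#' @param universe_size size of the gene universe.
#' @return an object of class \code{EnrichmentResult} with fields
#'   \code{overlap}, \code{expected}, \code{fold} and \code{p_value}.
#' @export
binomial_enrichment <- function(predicted, reference, universe_size) {
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  .assert(length(predicted) > 0, "empty predicted set")
  .assert(universe_size >= length(union(predicted, reference)),
          "universe smaller than the union of the sets")
  overlap <- length(intersect(predicted, reference))
  expected <- length(predicted) * length(reference) / universe_size
  p <- stats::pbinom(overlap - 1L, size = length(predicted),
                     prob = length(reference) / universe_size,
                     lower.tail = FALSE)
  structure(list(overlap = overlap, expected = expected,
                 fold = overlap / expected, p_value = p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: overlap %d (expected %.3f), fold %.2f, p = %.3g\n",
              x$overlap, x$expected, x$fold, x$p_value))
  invisible(x)
}

#' Decoder gene importance by masked-subset scoring
#'
#' For every drug profile of the input cell type, draws seeded random gene
#' subsets, masks the input to each subset (all other genes set to 0), scores
#' the masked prediction against the observed target-cell profile by Pearson
#' correlation, keeps the best-scoring subsets, and counts how often each
#' gene appears in them. Genes the decoder relies on accumulate high counts.
#'
#' @param model a trained \code{cs_model}.
#' @param paired a \code{PairedSet} providing inputs and ground truth.
#' @param input_cell cell type whose profiles are masked and fed in.
#' @param target_cell cell type predicted and scored.
#' @param n_subsets random subsets per profile (default 100).
#' @param subset_size genes kept per subset (default 100).
#' @param top_k best subsets counted per profile (default 10).
#' @param seed seed for subset sampling.
#' @return an object of class \code{ImportanceRanking} with fields
#'   \code{counts} (named per-gene frequency) and \code{ranked} (genes by
#'   descending count, ties by gene order).
#' @export
decoder_gene_importance <- function(model, paired, input_cell, target_cell,
                                    n_subsets = 100L, subset_size = 100L,
                                    top_k = 10L, seed = 1L) {
  G <- model$config$input_dim
  .assert(subset_size <= G, "subset_size %d exceeds the gene space (%d)",
          subset_size, G)
  .assert(top_k <= n_subsets, "top_k cannot exceed n_subsets")
  .assert(all(c(input_cell, target_cell) %in% paired$cell_types),
          "cell type missing from the paired set")
  counts <- stats::setNames(numeric(G), model$gene_space)
  .with_seed(seed, {
    for (drug in paired$drugs) {
      x <- paired$mats[[input_cell]][, drug]
      truth <- paired$mats[[target_cell]][, drug]
      subsets <- lapply(seq_len(n_subsets), function(i) sample.int(G, subset_size))
      X <- matrix(0, n_subsets, G)
      for (i in seq_len(n_subsets)) X[i, subsets[[i]]] <- x[subsets[[i]]]
      P <- .predict_matrix(model, X, target_cell)
      scores <- apply(P, 1, function(p)
        if (stats::sd(p) > 0) stats::cor(p, truth) else -Inf)
      best <- order(scores, decreasing = TRUE)[seq_len(top_k)]
      for (i in best) counts[subsets[[i]]] <- counts[subsets[[i]]] + 1
    }
  })
  ranked <- model$gene_space[order(-counts)]
  structure(list(counts = counts, ranked = ranked), class = "ImportanceRanking")
}

#' Write an importance ranking or alignment matrix as TSV
#'
#' @param x an \code{ImportanceRanking} or \code{LatentAlignmentMatrix}.
#' @param path output path.
#' @export
write_interpretation_tsv <- function(x, path) {
  if (inherits(x, "ImportanceRanking")) {
    df <- data.frame(gene = x$ranked, count = x$counts[x$ranked])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "LatentAlignmentMatrix")) {
    utils::write.table(data.frame(drug = rownames(x$matrix), x$matrix,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else .stopf("unsupported object of class %s", paste(class(x), collapse = "/"))
  invisible(path)
}
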