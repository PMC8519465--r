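#' Model configuration
#'
#' Hyperparameters of the shared-encoder / per-cell-decoder denoising
#' autoencoder. Defaults follow the reference setting for 978-gene landmark
#' signatures: encoder dense layers 512 and 256, latent size 128 with an L1
#' activity penalty, input dropout 0.5, leaky-ReLU slope 0.2, tanh output,
#' Adam with learning rate 1e-4, batch size 128, early-stopping patience 5.
#' \code{max_epochs} is a safety cap on each training stage.
#'
#' @param input_dim number of genes G.
#' @param encoder_widths hidden-layer sizes of the encoder.
#' @param latent_dim bottleneck size (must be smaller than \code{input_dim}).
#' @param decoder_widths hidden-layer sizes of each decoder; by default the
#'   encoder widths in reverse order.
#' @param dropout_rate input dropout rate in [0, 1).
#' @param leaky_alpha negative-slope coefficient of the leaky-ReLU.
#' @param l1_latent weight of the L1 penalty on latent activations.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs cap on epochs per training stage.
#' @param seed integer seed controlling initialization and training shuffles.
#' @return an object of class \code{ModelConfig}.
#' @export
model_config <- function(input_dim, encoder_widths = c(512L, 256L),
                         latent_dim = 128L, decoder_widths = rev(encoder_widths),
                         dropout_rate = 0.5, leaky_alpha = 0.2, l1_latent = 1e-6,
                         learning_rate = 1e-4, batch_size = 128L, patience = 5L,
                         max_epochs = 200L, seed = 1L) {
  .assert(input_dim >= 2, "input_dim must be at least 2")
  .assert(latent_dim >= 1 && latent_dim < input_dim,
          "latent_dim must be a positive bottleneck smaller than input_dim")
  .assert(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must be in [0, 1)")
  .assert(leaky_alpha > 0, "leaky_alpha must be positive")
  .assert(l1_latent >= 0, "l1_latent must be nonnegative")
  .assert(learning_rate > 0 && batch_size >= 1 && patience >= 1 && max_epochs >= 0,
          "invalid optimizer settings")
  structure(list(input_dim = as.integer(input_dim),
                 encoder_widths = as.integer(encoder_widths),
                 latent_dim = as.integer(latent_dim),
                 decoder_widths = as.integer(decoder_widths),
                 dropout_rate = dropout_rate, leaky_alpha = leaky_alpha,
                 l1_latent = l1_latent, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "ModelConfig")
}

#' Build an untrained model
#'
#' Creates the shared encoder, one decoder per cell type and the shared
#' pretraining decoder, with seeded Glorot-uniform weights. The encoder is
#' dropout(input) followed by the configured dense leaky-ReLU layers down to
#' the latent layer; each decoder mirrors the encoder widths and ends in a
#' tanh output layer fed by the concatenation of its last hidden layer and
#' the (dropout-processed) input vector — the skip connection that lets part
#' of the input leak directly into the prediction.
#'
#' @param config a \code{\link{model_config}}.
#' @param cell_types character vector of one or more cell-type identifiers.
#' @param gene_space optional gene identifiers (length \code{input_dim}).
#' @return an object of class \code{cs_model} (untrained).
#' @export
build_model <- function(config, cell_types, gene_space = NULL) {
  .assert(inherits(config, "ModelConfig"), "config must be a ModelConfig")
  .assert(length(cell_types) >= 1, "need at least one cell type")
  .assert(!anyDuplicated(cell_types), "duplicate cell types")
  if (is.null(gene_space)) gene_space <- sprintf("g%04d", seq_len(config$input_dim))
  .assert(length(gene_space) == config$input_dim,
          "gene_space length %d != input_dim %d", length(gene_space), config$input_dim)
  G <- config$input_dim
  model <- .with_seed(config$seed, {
    enc <- .enc_init(G, config$encoder_widths, config$latent_dim)
    shared <- .dec_init(config$latent_dim, config$decoder_widths, G)
    decs <- lapply(cell_types, function(ct)
      .dec_init(config$latent_dim, config$decoder_widths, G))
    names(decs) <- cell_types
    list(enc = enc, shared = shared, decs = decs)
  })
  structure(list(config = config, gene_space = as.character(gene_space),
                 normalization_scale = NA_real_,
                 cell_types = as.character(cell_types),
                 encoder = model$enc, shared_decoder = model$shared,
                 decoders = model$decs, training_log = NULL,
                 audit_drugs = character(0), trained_stage = "untrained"),
            class = "cs_model")
}

#' @export
print.cs_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("cross-cell autoencoder (%s): %d genes -> [%s] -> latent %d",
                     " -> [%s] -> %d genes\n"),
              x$trained_stage, cfg$input_dim,
              paste(cfg$encoder_widths, collapse = ", "), cfg$latent_dim,
              paste(cfg$decoder_widths, collapse = ", "), cfg$input_dim))
  cat(sprintf("decoders: %s; %d parameters\n",
              paste(x$cell_types, collapse = ", "), model_param_count(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums weight-matrix and bias sizes over the encoder and the per-cell-type
#' decoders (the shared pretraining decoder is excluded unless requested).
#'
#' @param model a \code{cs_model}.
#' @param include_shared also count the shared pretraining decoder.
#' @return integer parameter count.
#' @export
model_param_count <- function(model, include_shared = FALSE) {
  count_tree <- function(x) {
    if (is.numeric(x)) return(length(x))
    sum(vapply(x, count_tree, numeric(1)))
  }
  n <- count_tree(model$encoder) + count_tree(model$decoders)
  if (include_shared) n <- n + count_tree(model$shared_decoder)
  as.integer(n)
}

# coerce profiles / vectors / matrices to an n x G row matrix
.as_input_matrix <- function(model, x) {
  v <- if (inherits(x, "Profile")) x$values else x
  G <- model$config$input_dim
  if (is.matrix(v)) {
    .assert(ncol(v) == G, "input has %d columns, model expects %d genes", ncol(v), G)
    return(v)
  }
  .assert(is.numeric(v), "input must be a Profile, numeric vector or matrix")
  .assert(length(v) == G, "input has length %d, model expects %d genes", length(v), G)
  matrix(v, nrow = 1)
}

#' Encode a profile into the latent space
#'
#' Deterministic inference pass (dropout disabled).
#'
#' @param model a \code{cs_model}.
#' @param x a \code{Profile}, numeric vector of length G, or an n x G matrix.
#' @return a numeric latent vector (or an n x latent matrix for matrix input).
#' @export
encode <- function(model, x) {
  X <- .as_input_matrix(model, x)
  Z <- .enc_forward(model$encoder, X, model$config$leaky_alpha)$z
  if (nrow(Z) == 1L && !is.matrix(x)) drop(Z) else Z
}

#' Decode a latent code through one cell-type decoder
#'
#' @param model a \code{cs_model}.
#' @param code numeric latent vector (or n x latent matrix).
#' @param skip_input the profile feeding the skip connection (at inference the
#'   full input profile), on the model's gene space.
#' @param cell_type which decoder to use.
#' @return numeric vector (or matrix) of length G with values in (-1, 1).
#' @export
decode <- function(model, code, skip_input, cell_type) {
  dec <- model$decoders[[cell_type]]
  if (is.null(dec))
    .stopf("no decoder for cell type '%s'; available: %s", cell_type,
           paste(names(model$decoders), collapse = ", "))
  Xs <- .as_input_matrix(model, skip_input)
  Z <- if (is.matrix(code)) code else matrix(code, nrow = 1)
  .assert(ncol(Z) == model$config$latent_dim, "latent code has wrong length")
  .assert(nrow(Z) == nrow(Xs), "code and skip_input batch sizes differ")
  Y <- .dec_forward(dec, Z, Xs, model$config$leaky_alpha)$Y
  if (nrow(Y) == 1L && !is.matrix(code)) drop(Y) else Y
}

#' Predict the response in another cell type
#'
#' Encodes the measured response (from any cell type, including ones never
#' seen in training) and decodes it with the target cell type's decoder, the
#' input profile feeding the skip connection. Fully deterministic.
#'
#' @param model a trained \code{cs_model}.
#' @param input_profile a \code{Profile} or numeric vector on the model's
#'   gene space, values in [-1, 1].
#' @param target_cell decoder to predict with.
#' @return numeric vector of length G (the predicted profile).
#' @export
predict_response <- function(model, input_profile, target_cell) {
  X <- .as_input_matrix(model, input_profile)
  fe <- .enc_forward(model$encoder, X, model$config$leaky_alpha)
  dec <- model$decoders[[target_cell]]
  if (is.null(dec))
    .stopf("no decoder for cell type '%s'; available: %s", target_cell,
           paste(names(model$decoders), collapse = ", "))
  Y <- .dec_forward(dec, fe$z, X, model$config$leaky_alpha)$Y
  if (nrow(Y) == 1L && !is.matrix(input_profile)) drop(Y) else Y
}

# batch prediction: X is n x G, returns n x G
.predict_matrix <- function(model, X, target_cell) {
  fe <- .enc_forward(model$encoder, X, model$config$leaky_alpha)
  .dec_forward(model$decoders[[target_cell]], fe$z, X, model$config$leaky_alpha)$Y
}

#' Predict from multiple input cell types
#'
#' Per-gene arithmetic mean of single-cell-type predictions for the same
#' drug, which improves accuracy when responses in several cell types are
#' available.
#'
#' @param model a trained \code{cs_model}.
#' @param inputs named list of input profiles (one per input cell type), all
#'   for the same drug.
#' @param target_cell decoder to predict with.
#' @return numeric vector of length G.
#' @export
predict_multi <- function(model, inputs, target_cell) {
  .assert(is.list(inputs) && length(inputs) >= 1, "inputs must be a non-empty list")
  preds <- lapply(inputs, function(p) {
    y <- predict_response(model, .pvalues(p), target_cell)
    as.numeric(y)
  })
  Reduce(`+`, preds) / length(preds)
}
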