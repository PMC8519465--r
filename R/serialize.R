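#' Save a model to a single archive
#'
#' The archive stores the configuration, gene space, normalization scale and
#' all weights, and round-trips bit-exactly: a loaded model produces
#' bit-identical predictions. Stored as an RDS file (no HDF5 backend is
#' available in this build).
#'
#' @param model a \code{cs_model}.
#' @param path output path (conventionally \code{.dcs}).
#' @export
save_model <- function(model, path) {
  .assert(inherits(model, "cs_model"), "model must be a cs_model")
  saveRDS(model, path)
  invisible(path)
}

#' Load a model archive
#'
#' @param path path written by \code{\link{save_model}}.
#' @return the \code{cs_model}.
#' @export
load_model <- function(path) {
  .assert(file.exists(path), "model archive not found: %s", path)
  model <- readRDS(path)
  .assert(inherits(model, "cs_model"), "%s does not contain a model archive", path)
  model
}

#' Export the model configuration as JSON
#'
#' Human-readable companion to the binary archive: configuration, cell types,
#' gene list and normalization scale.
#'
#' @param model a \code{cs_model}.
#' @param path output path.
#' @export
write_model_config_json <- function(model, path) {
  jsonlite::write_json(list(config = unclass(model$config),
                            cell_types = model$cell_types,
                            normalization_scale = model$normalization_scale,
                            trained_stage = model$trained_stage,
                            gene_space = model$gene_space),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
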