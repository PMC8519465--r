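#' Construct a profile set
#'
#' A \code{ProfileSet} holds perturbation-response signatures over a fixed,
#' ordered gene space: a genes x samples numeric matrix plus per-sample
#' annotations (perturbagen, cell type, timepoint, dose). All downstream
#' operations (averaging, normalization, pairing, model training) consume
#' this container.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes character vector of unique gene identifiers (defaults to
#'   \code{rownames(values)}).
#' @param meta data.frame with one row per column of \code{values} and columns
#'   \code{sample_id}, \code{pert_id}, \code{cell_id}, \code{pert_type},
#'   \code{pert_time}, \code{pert_dose}.
#' @param normalization_scale positive scale already applied to the values
#'   (\code{NA} if raw).
#' @return an object of class \code{ProfileSet}.
#' @export
profile_set <- function(values, genes = rownames(values), meta,
                        normalization_scale = NA_real_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .assert(!is.null(genes) && length(genes) == nrow(values),
          "gene identifiers must match the number of matrix rows")
  genes <- as.character(genes)
  .assert(!anyDuplicated(genes), "gene identifiers must be unique")
  need <- c("sample_id", "pert_id", "cell_id", "pert_type", "pert_time", "pert_dose")
  .assert(is.data.frame(meta) && all(need %in% names(meta)),
          "meta must be a data.frame with columns: %s", paste(need, collapse = ", "))
  .assert(nrow(meta) == ncol(values),
          "meta has %d rows but the matrix has %d columns", nrow(meta), ncol(values))
  key <- paste(meta$pert_id, meta$cell_id, meta$pert_time, meta$pert_dose, sep = "\r")
  .assert(!anyDuplicated(key),
          "duplicate (perturbagen, cell, timepoint, dose) conditions in meta")
  rownames(values) <- genes
  colnames(values) <- meta$sample_id
  meta <- as.data.frame(lapply(meta[need], as.character), stringsAsFactors = FALSE)
  structure(list(genes = genes, values = values, meta = meta,
                 normalization_scale = normalization_scale),
            class = "ProfileSet")
}

#' @export
print.ProfileSet <- function(x, ...) {
  cat(sprintf("ProfileSet: %d genes x %d profiles (%d perturbagens, %d cell types)%s\n",
              length(x$genes), ncol(x$values), length(unique(x$meta$pert_id)),
              length(unique(x$meta$cell_id)),
              if (is.na(x$normalization_scale)) "" else
                sprintf(", scale %.4g", x$normalization_scale)))
  invisible(x)
}

#' Construct a single profile
#'
#' @param values numeric vector of per-gene differential-expression scores.
#' @param genes gene identifiers matching \code{values}.
#' @param pert_id,cell_id,pert_type,pert_time,pert_dose condition annotations.
#' @return an object of class \code{Profile}.
#' @export
profile <- function(values, genes = names(values), pert_id = "unknown",
                    cell_id = "unknown", pert_type = "compound",
                    pert_time = "averaged", pert_dose = "averaged") {
  values <- as.numeric(values)
  if (!is.null(genes)) {
    .assert(length(genes) == length(values), "genes and values lengths differ")
    names(values) <- genes
  }
  structure(list(values = values, pert_id = pert_id, cell_id = cell_id,
                 pert_type = pert_type, pert_time = pert_time,
                 pert_dose = pert_dose),
            class = "Profile")
}

# pull a plain numeric vector out of a Profile / vector
.pvalues <- function(p) {
  if (inherits(p, "Profile")) return(p$values)
  .assert(is.numeric(p), "expected a Profile or numeric vector")
  p
}

#' Read a signature matrix from disk
#'
#' Supports GCT 1.3 text and plain TSV (first column gene identifiers, header
#' row of sample identifiers). GCTX (HDF5) is part of the interface but not
#' available in this build, as no HDF5 reader is installed. Values are taken
#' verbatim from the file; gene order follows file row order.
#'
#' @param path file path.
#' @param format one of \code{"tsv"}, \code{"gct"}, \code{"gctx"}.
#' @param metadata data.frame of per-sample annotations with a
#'   \code{sample_id} column matching the file's column headers plus
#'   \code{pert_id}, \code{cell_id}, \code{pert_type}, \code{pert_time},
#'   \code{pert_dose}; or the path to such a table as TSV.
#' @return a \code{ProfileSet}.
#' @export
read_matrix <- function(path, format = c("tsv", "gct", "gctx"), metadata) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "gctx")
    .stopf("GCTX (HDF5) reading is unsupported in this build; export to GCT or TSV")
  if (is.character(metadata))
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  parsed <- if (format == "gct") .parse_gct(path) else .parse_tsv_matrix(path)
  .assert("sample_id" %in% names(metadata), "metadata must contain sample_id")
  idx <- match(colnames(parsed$values), metadata$sample_id)
  if (anyNA(idx))
    .stopf("metadata is missing annotations for column(s): %s",
           paste(colnames(parsed$values)[is.na(idx)], collapse = ", "))
  profile_set(parsed$values, parsed$genes, metadata[idx, , drop = FALSE])
}

.parse_tsv_matrix <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) .stopf("malformed TSV %s: %s", path, conditionMessage(e)))
  .assert(ncol(df) >= 2, "TSV %s has no data columns", path)
  genes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values))
    .stopf("malformed TSV %s: non-numeric entries in data columns", path)
  rownames(values) <- genes
  list(genes = genes, values = values)
}

# GCT 1.3: line 1 "#1.3"; line 2 "nrow ncol [nrowmeta ncolmeta]"; header line;
# optional column-metadata lines; then one line per gene.
.parse_gct <- function(path) {
  lines <- readLines(path)
  .assert(length(lines) >= 3, "malformed GCT %s: fewer than 3 lines", path)
  if (!grepl("^#1\\.[23]", lines[1]))
    .stopf("malformed GCT %s: line 1 must be a #1.2/#1.3 version tag, got '%s'",
           path, lines[1])
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (anyNA(dims) || length(dims) < 2)
    .stopf("malformed GCT %s: line 2 must hold integer dimensions", path)
  nr <- dims[1]; nc <- dims[2]
  nrmeta <- if (length(dims) >= 3) dims[3] else 1L  # 1.2 carries a Description column
  ncmeta <- if (length(dims) >= 4) dims[4] else 0L
  header <- strsplit(lines[3], "\t")[[1]]
  .assert(length(header) == 1 + nrmeta + nc,
          "malformed GCT %s: header has %d fields, expected %d (line 3)",
          path, length(header), 1 + nrmeta + nc)
  sample_ids <- header[(2 + nrmeta):length(header)]
  first_data <- 4L + ncmeta
  .assert(length(lines) >= first_data + nr - 1,
          "malformed GCT %s: expected %d data rows, file ends early", path, nr)
  genes <- character(nr)
  values <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ln <- first_data + i - 1L
    fields <- strsplit(lines[ln], "\t")[[1]]
    if (length(fields) != 1 + nrmeta + nc)
      .stopf("malformed GCT %s: line %d has %d fields, expected %d",
             path, ln, length(fields), 1 + nrmeta + nc)
    genes[i] <- fields[1]
    v <- suppressWarnings(as.numeric(fields[(2 + nrmeta):length(fields)]))
    if (anyNA(v))
      .stopf("malformed GCT %s: non-numeric value on line %d", path, ln)
    values[i, ] <- v
  }
  rownames(values) <- genes
  colnames(values) <- sample_ids
  list(genes = genes, values = values)
}

#' Write a profile set as TSV (matrix + metadata sidecar)
#'
#' @param ps a \code{ProfileSet}.
#' @param path output path for the genes x samples matrix.
#' @param meta_path optional output path for the sample annotation TSV.
#' @export
write_profile_set_tsv <- function(ps, path, meta_path = NULL) {
  df <- data.frame(gene = ps$genes, ps$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(ps$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a profile set as GCT 1.3
#'
#' @inheritParams write_profile_set_tsv
#' @export
write_gct <- function(ps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(sprintf("%d\t%d\t0\t0", nrow(ps$values), ncol(ps$values)), con)
  writeLines(paste(c("id", colnames(ps$values)), collapse = "\t"), con)
  body <- apply(ps$values, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                                collapse = "\t"))
  writeLines(paste(ps$genes, body, sep = "\t"), con)
  invisible(path)
}

#' Average replicate signatures across timepoints and doses
#'
#' Collapses a profile set to one signature per (perturbagen, cell type) by
#' the unweighted per-gene arithmetic mean over all available timepoint and
#' dose conditions, the standard noise-reduction step before pairing drugs
#' across cell types. Timepoint and dose are set to \code{"averaged"}.
#'
#' @param ps a \code{ProfileSet}.
#' @return a \code{ProfileSet} with one profile per (perturbagen, cell type).
#' @export
average_condition_replicates <- function(ps) {
  .assert(inherits(ps, "ProfileSet"), "ps must be a ProfileSet")
  .assert(ncol(ps$values) > 0, "ps is empty")
  key <- paste(ps$meta$pert_id, ps$meta$cell_id, sep = "\r")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  values <- vapply(groups, function(idx)
    rowMeans(ps$values[, idx, drop = FALSE]), numeric(length(ps$genes)))
  first <- vapply(groups, `[`, integer(1), 1L)
  meta <- data.frame(
    sample_id = paste(ps$meta$pert_id[first], ps$meta$cell_id[first], sep = "_"),
    pert_id = ps$meta$pert_id[first],
    cell_id = ps$meta$cell_id[first],
    pert_type = ps$meta$pert_type[first],
    pert_time = "averaged",
    pert_dose = "averaged",
    stringsAsFactors = FALSE)
  profile_set(values, ps$genes, meta, ps$normalization_scale)
}

#' Normalize a profile set to [-1, 1] by the global maximum
#'
#' Divides every value by the single maximum absolute value of the whole
#' matrix, matching the tanh output range of the model. The scale is recorded
#' in the result (and later baked into trained models) so the transform can be
#' inverted and so external data can be mapped into the same coordinates.
#'
#' @param ps a \code{ProfileSet}.
#' @return the normalized \code{ProfileSet} with \code{normalization_scale} set.
#' @export
normalize_global <- function(ps) {
  .assert(inherits(ps, "ProfileSet"), "ps must be a ProfileSet")
  s <- max(abs(ps$values))
  .assert(is.finite(s) && s > 0, "normalization scale undefined: all-zero matrix")
  ps$values <- ps$values / s
  ps$normalization_scale <- if (is.na(ps$normalization_scale)) s else
    ps$normalization_scale * s
  ps
}

#' Invert global normalization
#'
#' @param ps a normalized \code{ProfileSet}.
#' @return the profile set on its original scale.
#' @export
denormalize_global <- function(ps) {
  .assert(!is.na(ps$normalization_scale), "profile set carries no normalization scale")
  ps$values <- ps$values * ps$normalization_scale
  ps$normalization_scale <- NA_real_
  ps
}

#' Build a complete drug x cell-type block
#'
#' Keeps only perturbagens measured in every one of the requested cell types
#' (set intersection), yielding the complete paired block used for training
#' and evaluation.
#'
#' @param ps an averaged \code{ProfileSet} (one profile per drug and cell).
#' @param cell_types character vector of two or more cell-type identifiers.
#' @return an object of class \code{PairedSet} with fields \code{genes},
#'   \code{cell_types}, \code{drugs} and \code{mats} (per cell type a
#'   genes x drugs matrix with identical drug column order).
#' @export
build_paired_set <- function(ps, cell_types) {
  .assert(inherits(ps, "ProfileSet"), "ps must be a ProfileSet")
  .assert(length(cell_types) >= 2, "need at least two cell types")
  key <- paste(ps$meta$pert_id, ps$meta$cell_id, sep = "\r")
  .assert(!anyDuplicated(key),
          "ps must be averaged first: multiple profiles per (drug, cell)")
  missing <- setdiff(cell_types, unique(ps$meta$cell_id))
  if (length(missing))
    .stopf("cell type(s) absent from the profile set: %s",
           paste(missing, collapse = ", "))
  per_cell <- lapply(cell_types, function(ct)
    ps$meta$pert_id[ps$meta$cell_id == ct])
  drugs <- Reduce(intersect, per_cell)
  .assert(length(drugs) > 0, "no perturbagen is shared by all requested cell types")
  drugs <- sort(drugs)
  mats <- lapply(cell_types, function(ct) {
    idx <- match(paste(drugs, ct, sep = "\r"), key)
    m <- ps$values[, idx, drop = FALSE]
    colnames(m) <- drugs
    m
  })
  names(mats) <- cell_types
  structure(list(genes = ps$genes, cell_types = cell_types, drugs = drugs,
                 mats = mats, normalization_scale = ps$normalization_scale),
            class = "PairedSet")
}

#' @export
print.PairedSet <- function(x, ...) {
  cat(sprintf("PairedSet: %d drugs x %d cell types (%s) over %d genes\n",
              length(x$drugs), length(x$cell_types),
              paste(x$cell_types, collapse = ", "), length(x$genes)))
  invisible(x)
}

# restrict a PairedSet to a drug subset (fold construction)
paired_subset <- function(paired, drugs) {
  .assert(all(drugs %in% paired$drugs), "unknown drug in subset")
  paired$drugs <- drugs
  paired$mats <- lapply(paired$mats, function(m) m[, drugs, drop = FALSE])
  paired
}

#' Convert CAGE tag counts to landmark-space log fold-change profiles
#'
#' Per replicate, a pseudo-count is added to every gene and the column is
#' scaled to counts per million; replicates are averaged within condition and
#' each treatment is expressed as per-gene log2(treatment / control). Genes of
#' the landmark space absent from the count table are set to 0; genes outside
#' the landmark space are dropped. Matching is by exact symbol after
#' upper-casing.
#'
#' @param counts nonnegative numeric matrix of tag counts, genes in rows
#'   (rownames), samples in columns.
#' @param conditions character vector, one entry per column of \code{counts};
#'   replicates share a condition label.
#' @param gene_space character vector of landmark gene identifiers defining
#'   the output space.
#' @param pseudo_count value added to every gene count before scaling
#'   (default 2).
#' @param control name of the control condition (default \code{"control"}).
#' @param cell_id cell-type annotation for the output profiles.
#' @return a \code{ProfileSet} over \code{gene_space} with one profile per
#'   non-control condition.
#' @export
cage_counts_to_profiles <- function(counts, conditions, gene_space,
                                    pseudo_count = 2, control = "control",
                                    cell_id = "external") {
  counts <- as.matrix(counts)
  .assert(all(is.finite(counts)) && all(counts >= 0), "counts must be nonnegative")
  .assert(length(conditions) == ncol(counts),
          "conditions must annotate every count column")
  .assert(control %in% conditions, "missing control condition '%s'", control)
  .assert(pseudo_count > 0, "pseudo_count must be positive")
  pc <- counts + pseudo_count
  cpm <- sweep(pc, 2, colSums(pc), function(v, s) v * 1e6 / s)
  cond_means <- vapply(unique(conditions), function(cc)
    rowMeans(cpm[, conditions == cc, drop = FALSE]), numeric(nrow(counts)))
  ctrl <- cond_means[, control]
  treatments <- setdiff(unique(conditions), control)
  .assert(length(treatments) > 0, "no treatment condition present")
  idx <- match(toupper(gene_space), toupper(rownames(counts)))
  values <- vapply(treatments, function(tr) {
    lfc <- log2(cond_means[, tr] / ctrl)
    out <- numeric(length(gene_space))
    out[!is.na(idx)] <- lfc[idx[!is.na(idx)]]
    out
  }, numeric(length(gene_space)))
  meta <- data.frame(sample_id = paste(treatments, cell_id, sep = "_"),
                     pert_id = treatments, cell_id = cell_id,
                     pert_type = "compound", pert_time = "averaged",
                     pert_dose = "averaged", stringsAsFactors = FALSE)
  profile_set(values, gene_space, meta)
}

#' Log fold change between control and treatment means
#'
#' @param control_mean,treatment_mean strictly positive per-gene mean
#'   expression vectors of equal length.
#' @param genes gene identifiers for the input vectors (defaults to
#'   \code{names(control_mean)}).
#' @param gene_space optional landmark space to project onto; unmatched
#'   landmark genes get 0 (matching is by upper-cased symbol).
#' @param ... annotations passed to \code{\link{profile}}.
#' @return a \code{Profile} of per-gene log2(treatment / control).
#' @export
logfc_profile <- function(control_mean, treatment_mean,
                          genes = names(control_mean), gene_space = NULL, ...) {
  .assert(length(control_mean) == length(treatment_mean),
          "control and treatment vectors differ in length")
  .assert(all(control_mean > 0), "nonpositive control value; apply an offset first")
  .assert(all(treatment_mean > 0), "nonpositive treatment value; apply an offset first")
  lfc <- log2(treatment_mean / control_mean)
  if (is.null(gene_space)) return(profile(lfc, genes, ...))
  .assert(!is.null(genes), "genes required to project onto a gene space")
  idx <- match(toupper(gene_space), toupper(genes))
  out <- numeric(length(gene_space))
  out[!is.na(idx)] <- lfc[idx[!is.na(idx)]]
  profile(out, gene_space, ...)
}

#' Keep only one timepoint of a profile set
#'
#' External validation sets are restricted to the 24 h timepoint by default,
#' the dominant timepoint of the training corpus.
#'
#' @param ps a \code{ProfileSet}.
#' @param timepoint timepoint label to keep (default \code{"24 h"}).
#' @return the filtered \code{ProfileSet}.
#' @export
filter_timepoint <- function(ps, timepoint = "24 h") {
  keep <- ps$meta$pert_time == timepoint
  .assert(any(keep), "no profile at timepoint '%s'", timepoint)
  profile_set(ps$values[, keep, drop = FALSE], ps$genes,
              ps$meta[keep, , drop = FALSE], ps$normalization_scale)
}

#' Map external profiles into a trained model's coordinates
#'
#' External profiles are divided by the model's stored training scale (never
#' re-normalized by their own maximum) and clipped to [-1, 1], so they enter
#' the exact coordinate system the model was trained in.
#'
#' @param ps a \code{ProfileSet} on the model's gene space.
#' @param model a trained model carrying \code{normalization_scale}.
#' @return the rescaled \code{ProfileSet}.
#' @export
rescale_to_model <- function(ps, model) {
  s <- model$normalization_scale
  .assert(is.finite(s) && s > 0, "model carries no normalization scale")
  ps$values <- pmin(pmax(ps$values / s, -1), 1)
  ps$normalization_scale <- s
  ps
}
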