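#' Pearson correlation coefficient
#'
#' Direct covariance-over-sigmas implementation used for all accuracy
#' metrics. Errors (rather than silently returning 0 or NA) when either
#' vector is constant.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearson_cc <- function(x, y) {
  x <- .pvalues(x)
  y <- .pvalues(y)
  .assert(length(x) == length(y), "vectors differ in length (%d vs %d)",
          length(x), length(y))
  .assert(length(x) >= 3, "need at least 3 observations")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc * xc)
  sy <- sum(yc * yc)
  .assert(sx > 0 && sy > 0, "zero variance: correlation undefined")
  r <- sum(xc * yc) / sqrt(sx * sy)
  min(1, max(-1, r))
}

#' Baseline correlation: input profile as the prediction
#'
#' The naive cross-cell baseline predicts that the response in the target
#' cell type equals the measured response in the input cell type; its score
#' is the correlation between the two observed profiles.
#'
#' @param input_profile,truth profiles on the same gene space.
#' @return Pearson correlation.
#' @export
baseline_pcc <- function(input_profile, truth) {
  pearson_cc(.pvalues(input_profile), .pvalues(truth))
}

# fold-change over baseline; undefined (NA) when the baseline is at or below
# epsilon, to keep near-zero denominators out of the average
.fold_change <- function(pcc_pred, pcc_baseline, eps = 0.01) {
  ifelse(pcc_baseline > eps, pcc_pred / pcc_baseline, NA_real_)
}

.aggregate_rows <- function(rows) {
  defined <- !is.na(rows$fold_change)
  p <- if (nrow(rows) >= 3 && stats::sd(rows$pcc_pred - rows$pcc_baseline) > 0)
    stats::t.test(rows$pcc_pred, rows$pcc_baseline, paired = TRUE)$p.value
  else NA_real_
  list(mean_pcc_pred = mean(rows$pcc_pred),
       mean_pcc_baseline = mean(rows$pcc_baseline),
       mean_fold_change = if (any(defined)) mean(rows$fold_change[defined]) else NA_real_,
       n_fold_defined = sum(defined),
       p_value = p,
       n = nrow(rows))
}

.new_eval_report <- function(rows) {
  structure(list(rows = rows, aggregates = .aggregate_rows(rows)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(paste0("EvalReport: %d rows | mean PCC pred %.3f vs baseline %.3f",
                     " | mean fold-change %.2f (%d defined) | paired p = %.3g\n"),
              a$n, a$mean_pcc_pred, a$mean_pcc_baseline,
              a$mean_fold_change, a$n_fold_defined, a$p_value))
  invisible(x)
}

#' Evaluate predictions on a held-out drug block
#'
#' For every drug of the test block, predicts the target-cell response from
#' the given input cell types (averaging predictions when several inputs are
#' supplied), and scores prediction and baseline against the observed
#' target-cell profile. The baseline correlation is computed per input cell
#' and averaged. Aggregates include the paired two-sided t-test between
#' per-drug prediction and baseline correlations.
#'
#' @param model a trained \code{cs_model}.
#' @param test_block a \code{PairedSet} of held-out drugs containing the
#'   input and target cell types.
#' @param input_cells cell types whose profiles are used as input.
#' @param target_cell cell type to predict.
#' @return an \code{EvalReport}: \code{rows} (per-drug metrics) and
#'   \code{aggregates}.
#' @export
evaluate_predictions <- function(model, test_block, input_cells, target_cell) {
  .assert(target_cell %in% test_block$cell_types, "target cell missing from test block")
  .assert(all(input_cells %in% test_block$cell_types),
          "input cell missing from test block")
  .assert(target_cell %in% names(model$decoders), "no decoder for the target cell")
  overlap <- intersect(test_block$drugs, model$audit_drugs)
  .assert(length(overlap) == 0, "test drugs seen in training: %s",
          paste(utils::head(overlap, 5), collapse = ", "))
  rows <- list()
  skipped <- 0L
  for (drug in test_block$drugs) {
    truth <- test_block$mats[[target_cell]][, drug]
    inputs <- lapply(input_cells, function(ct) test_block$mats[[ct]][, drug])
    ok <- tryCatch({
      pred <- predict_multi(model, inputs, target_cell)
      pcc_pred <- pearson_cc(pred, truth)
      pcc_base <- mean(vapply(inputs, function(v) pearson_cc(v, truth), numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, input_cell = paste(input_cells, collapse = "+"),
        target_cell = target_cell, pcc_pred = pcc_pred, pcc_baseline = pcc_base,
        fold_change = .fold_change(pcc_pred, pcc_base),
        stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      warning(sprintf("drug '%s' skipped: undefined correlation", drug))
      skipped <- skipped + 1L
    }
  }
  .assert(length(rows) > 0, "no evaluable drug in the test block")
  rep <- .new_eval_report(do.call(rbind, rows))
  rep$aggregates$n_skipped <- skipped
  rep
}

# seeded partition of drugs into k folds of near-equal size
.partition_drugs <- function(drugs, k, seed) {
  .assert(k >= 2 && length(drugs) >= k, "need k >= 2 and at least k drugs")
  shuffled <- .with_seed(seed, sample(drugs))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

# assemble folds so that no family straddles train and test; greedy balance
.partition_families <- function(drugs, families, k, seed) {
  fam <- families[drugs]
  fam[is.na(fam)] <- paste0(".singleton.", drugs[is.na(fam)])
  groups <- split(drugs, fam)
  ord <- .with_seed(seed, sample(length(groups)))
  groups <- groups[ord]
  # largest-first greedy into the currently smallest fold, to keep folds
  # balanced even when one family is larger than |drugs|/k
  groups <- groups[order(-lengths(groups))]
  folds <- rep(list(character(0)), k)
  for (g in groups) {
    i <- which.min(lengths(folds))
    folds[[i]] <- c(folds[[i]], g)
  }
  if (max(lengths(folds)) > ceiling(length(drugs) / k) + 1)
    message("fold sizes rebalanced around a large drug family")
  folds
}

# train on all but the fold's drugs, evaluate each ordered direction pair
.run_fold <- function(paired, test_drugs, config, validation_fraction, seed) {
  train_drugs <- setdiff(paired$drugs, test_drugs)
  stopifnot(length(intersect(train_drugs, test_drugs)) == 0)
  model <- train_full_model(paired_subset(paired, train_drugs), config,
                            validation_fraction, seed = seed)
  test_block <- paired_subset(paired, sort(test_drugs))
  dirs <- expand.grid(input = paired$cell_types, target = paired$cell_types,
                      stringsAsFactors = FALSE)
  dirs <- dirs[dirs$input != dirs$target, , drop = FALSE]
  rows <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(i)
    evaluate_predictions(model, test_block, dirs$input[i], dirs$target[i])$rows))
  .new_eval_report(rows)
}

#' Drug-holdout k-fold cross-validation
#'
#' Partitions drugs into k disjoint folds (seeded shuffle); for each fold,
#' runs the full three-stage training on the remaining drugs (with an
#' internal validation split for early stopping) and evaluates the held-out
#' drugs in every ordered (input cell, target cell) direction. When a
#' drug-family map is supplied, delegates to \code{\link{holdout_families}}
#' so that drugs sharing a mode of action never straddle train and test.
#'
#' @param data a normalized \code{PairedSet}.
#' @param k number of folds (default 10).
#' @param config a \code{\link{model_config}}.
#' @param seed seed controlling the partition and per-fold training.
#' @param families optional named vector drug -> family identifier.
#' @param validation_fraction internal early-stopping split.
#' @return list with \code{folds} (per-fold \code{EvalReport}s),
#'   \code{pooled} (all rows combined), and \code{assignments}.
#' @export
crossval_by_drug <- function(data, k = 10L, config, seed = 1L, families = NULL,
                             validation_fraction = 0.1) {
  if (!is.null(families))
    return(holdout_families(data, families, k = k, config = config, seed = seed,
                            validation_fraction = validation_fraction))
  folds <- .partition_drugs(data$drugs, k, seed)
  .crossval_run(data, folds, config, seed, validation_fraction)
}

#' Drug-family holdout cross-validation
#'
#' @param data a normalized \code{PairedSet}.
#' @param families named character vector mapping drug -> family identifier;
#'   drugs absent from the map are treated as singleton families.
#' @inheritParams crossval_by_drug
#' @return as \code{\link{crossval_by_drug}}.
#' @export
holdout_families <- function(data, families, k = 10L, config, seed = 1L,
                             validation_fraction = 0.1) {
  folds <- .partition_families(data$drugs, families, k, seed)
  .crossval_run(data, folds, config, seed, validation_fraction)
}

.crossval_run <- function(data, folds, config, seed, validation_fraction) {
  reports <- lapply(seq_along(folds), function(i)
    .run_fold(data, folds[[i]], config, validation_fraction,
              seed = .child_seed(seed, 10L + i)))
  pooled <- .new_eval_report(do.call(rbind, lapply(reports, `[[`, "rows")))
  list(folds = reports, pooled = pooled, assignments = folds)
}

#' Write an evaluation report
#'
#' Rows as TSV plus a JSON summary of the aggregates.
#'
#' @param report an \code{EvalReport}.
#' @param tsv_path,json_path output paths (either may be NULL).
#' @export
write_eval_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report$rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$aggregates, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}

#' Read a drug-family map
#'
#' Two-column TSV (drug, family).
#'
#' @param path file path.
#' @return named character vector drug -> family.
#' @export
read_family_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "family map must have two columns (drug, family)")
  .assert(!anyDuplicated(df[[1]]), "a drug appears in more than one family")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
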