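#' Training plan
#'
#' Splits the drugs of a paired set into training and validation (by drug,
#' never by profile, so the same drug cannot sit on both sides of the split in
#' different cell types) and fixes the round-robin decoder order.
#'
#' @param paired a \code{\link{build_paired_set}} result.
#' @param validation_fraction fraction of drugs held out for early stopping
#'   (default 0.1; 0 disables early stopping).
#' @param stage_order cell-type order for round-robin decoder training.
#' @param seed integer seed for the validation split.
#' @return an object of class \code{TrainingPlan}.
#' @export
training_plan <- function(paired, validation_fraction = 0.1,
                          stage_order = paired$cell_types, seed = 1L) {
  .assert(inherits(paired, "PairedSet"), "paired must be a PairedSet")
  .assert(validation_fraction >= 0 && validation_fraction < 1,
          "validation_fraction must be in [0, 1)")
  .assert(all(stage_order %in% paired$cell_types), "unknown cell type in stage_order")
  D <- length(paired$drugs)
  n_val <- if (validation_fraction > 0) max(1L, round(validation_fraction * D)) else 0L
  .assert(D - n_val >= 1, "not enough drugs to split off a validation set")
  val_drugs <- if (n_val > 0)
    .with_seed(seed, sort(sample(paired$drugs, n_val))) else character(0)
  structure(list(paired = paired, validation_fraction = validation_fraction,
                 stage_order = stage_order, seed = as.integer(seed),
                 train_drugs = setdiff(paired$drugs, val_drugs),
                 val_drugs = val_drugs),
            class = "TrainingPlan")
}

# profiles of `drugs` across all cells, as an n x G matrix (rows = profiles)
.stack_profiles <- function(paired, drugs, cells = paired$cell_types) {
  do.call(rbind, lapply(cells, function(ct) t(paired$mats[[ct]][, drugs, drop = FALSE])))
}

# mean reconstruction MSE of the shared autoencoder on X (dropout off)
.val_mse_shared <- function(enc, dec, X, alpha) {
  fe <- .enc_forward(enc, X, alpha)
  mean((.dec_forward(dec, fe$z, X, alpha)$Y - X)^2)
}

# pooled cross-cell validation MSE: every (input cell -> target cell) pair of
# the validation drugs through the target's decoder, dropout off
.val_mse_cross <- function(enc, decs, paired, drugs, alpha) {
  if (!length(drugs)) return(NA_real_)
  errs <- c()
  for (tgt in names(decs)) {
    Y <- t(paired$mats[[tgt]][, drugs, drop = FALSE])
    for (src in paired$cell_types) {
      X <- t(paired$mats[[src]][, drugs, drop = FALSE])
      fe <- .enc_forward(enc, X, alpha)
      P <- .dec_forward(decs[[tgt]], fe$z, X, alpha)$Y
      errs <- c(errs, mean((P - Y)^2))
    }
  }
  mean(errs)
}

# One minibatch gradient step on (Xb -> Yb) through decoder `dec`; `st` is a
# mutable environment holding enc, dec params, adam states and step counter.
.batch_step <- function(st, Xb, Yb, cfg, freeze_encoder = FALSE) {
  Xd <- .apply_dropout(Xb, cfg$dropout_rate)
  fe <- .enc_forward(st$enc, Xd, cfg$leaky_alpha)
  fd <- .dec_forward(st$dec, fe$z, Xd, cfg$leaky_alpha)
  dY <- 2 * (fd$Y - Yb) / length(Yb)
  g <- .net_backward(st$enc, st$dec, Xd, fe, fd, dY, cfg$leaky_alpha,
                     l1 = cfg$l1_latent, freeze_encoder = freeze_encoder)
  st$t <- st$t + 1L
  if (!freeze_encoder) {
    r <- .adam_apply(st$enc, g$enc, st$enc_adam, cfg$learning_rate, st$t)
    st$enc <- r$p
    st$enc_adam <- r$s
  }
  r <- .adam_apply(st$dec, g$dec, st$dec_adam, cfg$learning_rate, st$t)
  st$dec <- r$p
  st$dec_adam <- r$s
  mean((fd$Y - Yb)^2) + cfg$l1_latent * sum(abs(fe$z)) / nrow(Xb)
}

# iterate minibatches over shuffled rows; returns mean train loss
.run_epoch <- function(st, X, Y, cfg, freeze_encoder = FALSE) {
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)
  ord <- sample.int(n)
  losses <- c()
  for (start in seq(1, n, by = bs)) {
    idx <- ord[start:min(start + bs - 1, n)]
    losses <- c(losses, .batch_step(st, X[idx, , drop = FALSE],
                                    Y[idx, , drop = FALSE], cfg, freeze_encoder))
  }
  mean(losses)
}

#' Stage 1: pretrain the joint autoencoder
#'
#' Trains the shared encoder plus a single shared decoder on identity
#' reconstruction, pooling the profiles of all cell types as both input and
#' target. The input is corrupted by dropout, so the model learns to denoise.
#' Stops when the validation reconstruction loss has not improved for
#' \code{patience} epochs (best weights restored), or at \code{max_epochs}.
#'
#' @param model an untrained \code{cs_model} built for the plan's cell types.
#' @param plan a \code{\link{training_plan}}.
#' @return the model, pretrained, with \code{training_log} populated.
#' @export
pretrain_joint_autoencoder <- function(model, plan) {
  .assert(inherits(model, "cs_model"), "model must be a cs_model")
  .assert(inherits(plan, "TrainingPlan"), "plan must be a TrainingPlan")
  cfg <- model$config
  paired <- plan$paired
  .assert(all(model$cell_types %in% paired$cell_types) &&
            all(paired$cell_types %in% model$cell_types),
          "model and paired set disagree on cell types")
  X <- .stack_profiles(paired, plan$train_drugs)
  Xv <- if (length(plan$val_drugs)) .stack_profiles(paired, plan$val_drugs) else NULL
  if (nrow(X) < cfg$batch_size)
    warning(sprintf("only %d training profiles; batch size reduced from %d",
                    nrow(X), cfg$batch_size))
  st <- new.env(parent = emptyenv())
  st$enc <- model$encoder
  st$dec <- model$shared_decoder
  st$enc_adam <- .adam_state(st$enc)
  st$dec_adam <- .adam_state(st$dec)
  st$t <- 0L
  log <- list()
  .with_seed(.child_seed(plan$seed, 1L), {
    best <- list(enc = st$enc, dec = st$dec, val = Inf, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      tr <- .run_epoch(st, X, X, cfg)
      vl <- if (is.null(Xv)) NA_real_ else
        .val_mse_shared(st$enc, st$dec, Xv, cfg$leaky_alpha)
      log[[length(log) + 1L]] <- data.frame(epoch = epoch, stage = "pretrain",
                                            cell = NA_character_, train_mse = tr,
                                            val_mse = vl)
      if (!is.null(Xv)) {
        if (vl < best$val) {
          best <- list(enc = st$enc, dec = st$dec, val = vl, epoch = epoch)
          wait <- 0L
        } else wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    if (!is.null(Xv) && is.finite(best$val)) {
      st$enc <- best$enc
      st$dec <- best$dec
    }
  })
  model$encoder <- st$enc
  model$shared_decoder <- st$dec
  model$training_log <- rbind(model$training_log, do.call(rbind, log))
  # validation drugs steer early stopping, so they count as seen
  model$audit_drugs <- union(model$audit_drugs, paired$drugs)
  model$gene_space <- paired$genes
  if (!is.na(paired$normalization_scale))
    model$normalization_scale <- paired$normalization_scale
  model$trained_stage <- "pretrained"
  model
}

#' Stages 2 and 3: train the cell-type-specific decoders
#'
#' Stage 2 initializes every cell-type decoder as a copy of the pretrained
#' shared decoder, then trains them one by one in round-robin order together
#' with the shared encoder: for decoder c, the training pairs map the profile
#' of drug d in any cell type to the profile of d in cell type c. When the
#' pooled cross-cell validation loss has not improved for \code{patience}
#' rounds, stage 3 freezes the encoder and continues training the decoders
#' alone until validation again stops improving. Best-validation weights are
#' restored after each stage.
#'
#' @param model a pretrained \code{cs_model}.
#' @param plan the same \code{\link{training_plan}} used for pretraining.
#' @return the fully trained \code{cs_model}; \code{encoder_stage2} holds the
#'   encoder weights at the end of stage 2 (for freeze auditing).
#' @export
train_cell_decoders <- function(model, plan) {
  .assert(model$trained_stage %in% c("pretrained", "full"),
          "model must be pretrained first (see pretrain_joint_autoencoder)")
  cfg <- model$config
  paired <- plan$paired
  for (ct in model$cell_types)
    .assert(ct %in% paired$cell_types, "cell type '%s' has no profiles", ct)
  alpha <- cfg$leaky_alpha
  decs <- lapply(model$cell_types, function(ct) model$shared_decoder)
  names(decs) <- model$cell_types
  enc <- model$encoder
  log <- list()

  run_stage <- function(stage_name, enc, decs, freeze_encoder, seed) {
    st <- new.env(parent = emptyenv())
    st$enc <- enc
    st$enc_adam <- .adam_state(enc)
    dec_adams <- lapply(decs, .adam_state)
    ts <- stats::setNames(rep(0L, length(decs)), names(decs))
    best <- list(enc = enc, decs = decs, val = Inf)
    wait <- 0L
    .with_seed(seed, {
      for (round in seq_len(cfg$max_epochs)) {
        for (ct in plan$stage_order) {
          X <- .stack_profiles(paired, plan$train_drugs)
          Ytgt <- t(paired$mats[[ct]][, plan$train_drugs, drop = FALSE])
          Y <- do.call(rbind, rep(list(Ytgt), length(paired$cell_types)))
          st$dec <- decs[[ct]]
          st$dec_adam <- dec_adams[[ct]]
          st$t <- ts[[ct]]
          tr <- .run_epoch(st, X, Y, cfg, freeze_encoder)
          decs[[ct]] <- st$dec
          dec_adams[[ct]] <- st$dec_adam
          ts[[ct]] <- st$t
          log[[length(log) + 1L]] <<- data.frame(epoch = round, stage = stage_name,
                                                 cell = ct, train_mse = tr,
                                                 val_mse = NA_real_)
        }
        vl <- .val_mse_cross(st$enc, decs, paired, plan$val_drugs, alpha)
        log[[length(log)]]$val_mse <<- vl
        if (!is.na(vl)) {
          if (vl < best$val) {
            best <- list(enc = st$enc, decs = decs, val = vl)
            wait <- 0L
          } else wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    })
    if (is.finite(best$val)) list(enc = best$enc, decs = best$decs)
    else list(enc = st$enc, decs = decs)
  }

  s2 <- run_stage("decoders", enc, decs, FALSE, .child_seed(plan$seed, 2L))
  s3 <- run_stage("frozen", s2$enc, s2$decs, TRUE, .child_seed(plan$seed, 3L))
  stopifnot(identical(s2$enc, s3$enc))  # freeze contract

  model$encoder <- s3$enc
  model$encoder_stage2 <- s2$enc
  model$decoders <- s3$decs
  model$training_log <- rbind(model$training_log, do.call(rbind, log))
  model$audit_drugs <- union(model$audit_drugs, paired$drugs)
  model$trained_stage <- "full"
  model
}

#' Run the full three-stage protocol
#'
#' Convenience wrapper: builds the plan, pretrains the joint autoencoder and
#' trains the per-cell decoders.
#'
#' @param paired a normalized \code{PairedSet}.
#' @param config a \code{\link{model_config}} with matching \code{input_dim}.
#' @param validation_fraction drug fraction for early stopping.
#' @param seed seed for the split and all training randomness.
#' @return a trained \code{cs_model}.
#' @export
train_full_model <- function(paired, config, validation_fraction = 0.1, seed = 1L) {
  .assert(config$input_dim == length(paired$genes),
          "config input_dim %d != %d genes in the paired set",
          config$input_dim, length(paired$genes))
  config$seed <- as.integer(seed)
  model <- build_model(config, paired$cell_types, paired$genes)
  plan <- training_plan(paired, validation_fraction, seed = seed)
  model <- pretrain_joint_autoencoder(model, plan)
  train_cell_decoders(model, plan)
}

#' Transfer learning: fine-tune on a small external drug set
#'
#' Continues stage-2-style training (shared encoder plus decoders, cross-cell
#' pairs) on a small paired set, excluding one held-out drug entirely, with
#' early stopping on a validation split of the remaining drugs. The input
#' model is not modified; a fine-tuned copy is returned. With
#' \code{max_epochs = 0} in the model config the copy is returned unchanged.
#'
#' @param model a trained \code{cs_model}.
#' @param small_set a \code{PairedSet} whose cell types all have decoders.
#' @param held_out_drug drug to exclude from all fine-tuning pairs.
#' @param validation_fraction drug fraction of the small set used for early
#'   stopping.
#' @param seed seed for the fine-tuning randomness.
#' @return the fine-tuned \code{cs_model} copy.
#' @export
transfer_finetune <- function(model, small_set, held_out_drug,
                              validation_fraction = 0.1, seed = 1L) {
  .assert(model$trained_stage == "full", "model must be fully trained")
  .assert(held_out_drug %in% small_set$drugs,
          "held-out drug '%s' is not in the fine-tuning set", held_out_drug)
  .assert(all(small_set$cell_types %in% names(model$decoders)),
          "fine-tuning set contains cell types without decoders")
  rest <- setdiff(small_set$drugs, held_out_drug)
  .assert(length(rest) >= 2, "too few drugs left after holding out '%s'", held_out_drug)
  sub <- paired_subset(small_set, rest)
  cfg <- model$config
  tuned <- model
  tuned$audit_drugs <- union(tuned$audit_drugs, rest)
  if (cfg$max_epochs == 0L) return(tuned)
  plan <- training_plan(sub, validation_fraction, stage_order = sub$cell_types,
                        seed = seed)
  alpha <- cfg$leaky_alpha
  st <- new.env(parent = emptyenv())
  st$enc <- tuned$encoder
  st$enc_adam <- .adam_state(st$enc)
  decs <- tuned$decoders[sub$cell_types]
  dec_adams <- lapply(decs, .adam_state)
  ts <- stats::setNames(rep(0L, length(decs)), names(decs))
  log <- list()
  best <- list(enc = st$enc, decs = decs, val = Inf)
  wait <- 0L
  .with_seed(.child_seed(seed, 4L), {
    for (round in seq_len(cfg$max_epochs)) {
      for (ct in plan$stage_order) {
        X <- .stack_profiles(sub, plan$train_drugs)
        Ytgt <- t(sub$mats[[ct]][, plan$train_drugs, drop = FALSE])
        Y <- do.call(rbind, rep(list(Ytgt), length(sub$cell_types)))
        st$dec <- decs[[ct]]
        st$dec_adam <- dec_adams[[ct]]
        st$t <- ts[[ct]]
        tr <- .run_epoch(st, X, Y, cfg)
        decs[[ct]] <- st$dec
        dec_adams[[ct]] <- st$dec_adam
        ts[[ct]] <- st$t
        log[[length(log) + 1L]] <- data.frame(epoch = round, stage = "finetune",
                                              cell = ct, train_mse = tr,
                                              val_mse = NA_real_)
      }
      vl <- .val_mse_cross(st$enc, decs, sub, plan$val_drugs, alpha)
      log[[length(log)]]$val_mse <- vl
      if (!is.na(vl)) {
        if (vl < best$val) {
          best <- list(enc = st$enc, decs = decs, val = vl)
          wait <- 0L
        } else wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  if (is.finite(best$val)) {
    st$enc <- best$enc
    decs <- best$decs
  }
  tuned$encoder <- st$enc
  tuned$decoders[sub$cell_types] <- decs
  tuned$training_log <- rbind(tuned$training_log, do.call(rbind, log))
  tuned
}

#' Write the training log as TSV
#'
#' @param model a trained \code{cs_model}.
#' @param path output path.
#' @export
write_training_log <- function(model, path) {
  .assert(!is.null(model$training_log), "model has no training log")
  utils::write.table(model$training_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
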