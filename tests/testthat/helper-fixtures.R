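# Shared fixtures. Heavy objects (the default synthetic cohort and one
# trained scaled model) are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# the scaled model configuration used throughout the synthetic experiments:
# latent 32, widths [128, 64], 60-epoch cap, Adam 1e-3 (see methods vignette)
scaled_config <- function(n_genes = 200L, latent = 32L, max_epochs = 60L, seed = 1L) {
  model_config(input_dim = n_genes, encoder_widths = c(128L, 64L),
               latent_dim = latent, learning_rate = 1e-3,
               max_epochs = max_epochs, seed = seed)
}

# default synthetic fixture: 300 drugs, 2 cells, 200 genes, true k 16,
# shared_fraction 0.6, noise 0.3
default_cohort <- function() .memo("cohort", function() generate_cohort(seed = 1L))

# one trained scaled model on drugs 1..270 of the default fixture, with the
# last 30 drugs held out as a test block
trained_fixture <- function() .memo("trained", function() {
  res <- default_cohort()
  paired <- res$paired
  train <- cellstate:::paired_subset(paired, paired$drugs[1:270])
  test <- cellstate:::paired_subset(paired, paired$drugs[271:300])
  list(model = train_full_model(train, scaled_config(), seed = 1L),
       train = train, test = test, truth = res$truth)
})

# a small profile set with replicated conditions for the IO tests
tiny_profile_set <- function() {
  values <- matrix(c(1, 3, 5,
                     3, 5, 7,
                     2, 2, 2,
                     4, 6, 8), nrow = 3,
                   dimnames = list(NULL, paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     pert_id = c("drugA", "drugA", "drugB", "drugB"),
                     cell_id = c("MCF7", "MCF7", "MCF7", "PC3"),
                     pert_type = "compound",
                     pert_time = c("6 h", "24 h", "24 h", "24 h"),
                     pert_dose = c("10 uM", "10 uM", "10 uM", "10 uM"),
                     stringsAsFactors = FALSE)
  profile_set(values, paste0("g", 1:3), meta)
}

# a deterministic hand-set micro network: G = 4, one 3-wide encoder layer,
# latent 2, one 3-wide decoder layer; every weight set to a known constant
# pattern so forward passes can be recomputed longhand in tests
handset_model <- function() {
  cfg <- model_config(input_dim = 4L, encoder_widths = 3L, latent_dim = 2L,
                      decoder_widths = 3L, dropout_rate = 0, seed = 1L)
  m <- build_model(cfg, "X")
  fill <- function(mat, v) matrix(v, nrow(mat), ncol(mat))
  m$encoder[[1]]$W <- fill(m$encoder[[1]]$W, 0.1)
  m$encoder[[1]]$b <- rep(0.05, 3)
  m$encoder[[2]]$W <- fill(m$encoder[[2]]$W, -0.2)
  m$encoder[[2]]$b <- rep(0.1, 2)
  m$decoders$X$hidden[[1]]$W <- fill(m$decoders$X$hidden[[1]]$W, 0.3)
  m$decoders$X$hidden[[1]]$b <- rep(-0.05, 3)
  m$decoders$X$out$W <- fill(m$decoders$X$out$W, 0.15)
  m$decoders$X$out$b <- rep(0.02, 4)
  m
}

# independent longhand leaky-ReLU used by forward-pass oracles
oracle_lrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
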