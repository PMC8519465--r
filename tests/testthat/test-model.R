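test_that("model construction follows the declared architecture", {
  cfg <- model_config(input_dim = 10L, encoder_widths = c(6L, 4L),
                      latent_dim = 3L, seed = 2L)
  m <- build_model(cfg, c("MCF7", "PC3"))
  expect_length(m$decoders, 2L)
  expect_named(m$decoders, c("MCF7", "PC3"))
  expect_length(m$encoder, 3L)  # two hidden layers + latent layer
  expect_length(encode(m, rnorm(10)), 3L)
  # parameter-count oracle: sum of in*out + out over declared layers,
  # including the (last_width + G) x G skip-fed output layer, per decoder
  enc_p <- (10 * 6 + 6) + (6 * 4 + 4) + (4 * 3 + 3)
  dec_p <- (3 * 4 + 4) + (4 * 6 + 6) + ((6 + 10) * 10 + 10)
  expect_equal(model_param_count(m), enc_p + 2 * dec_p)
  expect_error(model_config(input_dim = 10L, latent_dim = 10L), "bottleneck")
})

test_that("encode is deterministic and maps zero input to a zero code", {
  cfg <- model_config(input_dim = 8L, encoder_widths = 5L, latent_dim = 2L,
                      seed = 4L)
  m <- build_model(cfg, "A")
  x <- rnorm(8)
  expect_identical(encode(m, x), encode(m, x))
  # fresh biases are zero and leaky-ReLU(0) = 0
  expect_equal(encode(m, rep(0, 8)), rep(0, 2))
  expect_error(encode(m, rnorm(5)), "expects 8 genes")
})

test_that("forward passes match a longhand computation on a hand-set network", {
  m <- handset_model()
  x <- c(0.5, -0.25, 0.1, -0.6)
  # longhand: every encoder weight 0.1 (bias 0.05), second layer -0.2 (0.1)
  h1 <- oracle_lrelu(rep(sum(x) * 0.1 + 0.05, 3))
  z <- oracle_lrelu(rep(sum(h1) * -0.2 + 0.1, 2))
  expect_equal(encode(m, x), z)
  # decoder: hidden 0.3 (-0.05), output 0.15 (0.02) over cbind(hidden, skip)
  d1 <- oracle_lrelu(rep(sum(z) * 0.3 - 0.05, 3))
  out <- tanh(rep(sum(d1) * 0.15 + sum(x) * 0.15 + 0.02, 4))
  expect_equal(decode(m, z, x, "X"), out)
  expect_equal(predict_response(m, x, "X"), out)
})

test_that("decode stays strictly inside (-1, 1) and validates the cell type", {
  cfg <- model_config(input_dim = 12L, encoder_widths = 6L, latent_dim = 3L,
                      seed = 9L)
  m <- build_model(cfg, c("A", "B"))
  for (i in 1:5) {
    y <- decode(m, rnorm(3, sd = 10), runif(12, -1, 1), "A")
    expect_true(all(y > -1 & y < 1))
  }
  y1 <- decode(m, c(1, 2, 3), rep(0.5, 12), "B")
  expect_identical(y1, decode(m, c(1, 2, 3), rep(0.5, 12), "B"))
  expect_error(decode(m, c(1, 2, 3), rep(0.5, 12), "C"), "available: A, B")
})

test_that("prediction dimensionality is G for any input cell, incl. self-map", {
  fx <- trained_fixture()
  m <- fx$model
  x <- fx$test$mats$cellA[, 1]
  expect_length(predict_response(m, x, "cellA"), 200L)  # denoising self-map
  expect_length(predict_response(m, x, "cellB"), 200L)
  # an input from a cell type never seen in training still predicts
  unseen <- tanh(rnorm(200))
  expect_length(predict_response(m, unseen, "cellB"), 200L)
})

test_that("multi-input prediction is the mean of single predictions", {
  fx <- trained_fixture()
  m <- fx$model
  xa <- fx$test$mats$cellA[, 2]
  xb <- fx$test$mats$cellB[, 2]
  expect_equal(predict_multi(m, list(xa), "cellB"),
               as.numeric(predict_response(m, xa, "cellB")))
  p <- predict_response(m, xa, "cellB")
  q <- predict_response(m, xb, "cellB")
  expect_equal(predict_multi(m, list(xa, xb), "cellB"), as.numeric((p + q) / 2))
  # brute-force mean over k inputs
  inputs <- lapply(1:4, function(i) tanh(rnorm(200) / 2))
  brute <- rowMeans(sapply(inputs, function(x)
    predict_response(m, x, "cellA")))
  expect_equal(predict_multi(m, inputs, "cellA"), brute)
  expect_error(predict_multi(m, list(), "cellA"), "non-empty")
})

test_that("backpropagation matches numerical gradients on a small network", {
  cfg <- model_config(input_dim = 6L, encoder_widths = 4L, latent_dim = 2L,
                      decoder_widths = 3L, dropout_rate = 0, l1_latent = 1e-3,
                      seed = 11L)
  m <- build_model(cfg, "A")
  set.seed(1)
  X <- matrix(runif(18, -1, 1), 3, 6)
  Y <- matrix(runif(18, -1, 1), 3, 6)
  loss_at <- function(enc, dec) {
    fe <- cellstate:::.enc_forward(enc, X, cfg$leaky_alpha)
    fd <- cellstate:::.dec_forward(dec, fe$z, X, cfg$leaky_alpha)
    mean((fd$Y - Y)^2) + cfg$l1_latent * sum(abs(fe$z)) / nrow(X)
  }
  fe <- cellstate:::.enc_forward(m$encoder, X, cfg$leaky_alpha)
  fd <- cellstate:::.dec_forward(m$decoders$A, fe$z, X, cfg$leaky_alpha)
  dY <- 2 * (fd$Y - Y) / length(Y)
  g <- cellstate:::.net_backward(m$encoder, m$decoders$A, X, fe, fd, dY,
                                 cfg$leaky_alpha, l1 = cfg$l1_latent,
                                 want_input_grad = TRUE)
  eps <- 1e-6
  num_grad <- function(get, set) {
    w <- get(m)
    out <- w
    for (i in seq_along(w)) {
      wp <- w; wp[i] <- wp[i] + eps
      wm <- w; wm[i] <- wm[i] - eps
      out[i] <- (loss_at(set(m, wp)$encoder, set(m, wp)$decoders$A) -
                 loss_at(set(m, wm)$encoder, set(m, wm)$decoders$A)) / (2 * eps)
    }
    out
  }
  # encoder layer-1 weights
  gn <- num_grad(function(m) m$encoder[[1]]$W,
                 function(m, w) { m$encoder[[1]]$W <- w; m })
  expect_equal(g$enc[[1]]$W, gn, tolerance = 1e-5)
  # latent layer bias (carries the L1 path)
  gn <- num_grad(function(m) m$encoder[[2]]$b,
                 function(m, w) { m$encoder[[2]]$b <- w; m })
  expect_equal(g$enc[[2]]$b, gn, tolerance = 1e-5)
  # decoder output weights (skip-fed layer)
  gn <- num_grad(function(m) m$decoders$A$out$W,
                 function(m, w) { m$decoders$A$out$W <- w; m })
  expect_equal(g$dec$out$W, gn, tolerance = 1e-5)
  # decoder hidden weights
  gn <- num_grad(function(m) m$decoders$A$hidden[[1]]$W,
                 function(m, w) { m$decoders$A$hidden[[1]]$W <- w; m })
  expect_equal(g$dec$hidden[[1]]$W, gn, tolerance = 1e-5)
})

test_that("input gradients (skip + encoder paths) match numerical gradients", {
  cfg <- model_config(input_dim = 5L, encoder_widths = 4L, latent_dim = 2L,
                      decoder_widths = 3L, dropout_rate = 0, seed = 12L)
  m <- build_model(cfg, "A")
  set.seed(2)
  x <- runif(5, -0.5, 0.5)
  out_at <- function(x) {
    X <- matrix(x, 1)
    fe <- cellstate:::.enc_forward(m$encoder, X, cfg$leaky_alpha)
    cellstate:::.dec_forward(m$decoders$A, fe$z, X, cfg$leaky_alpha)$Y[1, 3]
  }
  ob <- cellstate:::.tf_objective(m, x, 3L, "A")
  eps <- 1e-6
  gn <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (out_at(xp) - out_at(xm)) / (2 * eps)
  }, numeric(1))
  expect_equal(ob$grad, gn, tolerance = 1e-5)
})

test_that("models serialize and round-trip bit-exact predictions", {
  fx <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".dcs")
  save_model(fx$model, path)
  m2 <- load_model(path)
  x <- fx$test$mats$cellA[, 5]
  expect_identical(predict_response(fx$model, x, "cellB"),
                   predict_response(m2, x, "cellB"))
  expect_identical(fx$model$encoder, m2$encoder)
  cfg_json <- withr::local_tempfile(fileext = ".json")
  write_model_config_json(fx$model, cfg_json)
  parsed <- jsonlite::read_json(cfg_json)
  expect_equal(parsed$config$latent_dim, 32L)
  expect_equal(length(parsed$gene_space), 200L)
})
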