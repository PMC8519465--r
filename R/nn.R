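# Dense-network primitives for the shared-encoder / per-cell-decoder
# autoencoder: Glorot initialization, leaky-ReLU / tanh forward passes,
# manual backpropagation (including the input-skip path into the output
# layer) and an Adam optimizer. Everything operates on plain numeric
# matrices so that seeded runs are bit-reproducible.

.lrelu <- function(x, alpha) {
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  x
}

# derivative of leaky-ReLU evaluated at the pre-activation
.lrelu_g <- function(pre, alpha) (pre > 0) + alpha * (pre <= 0)

# add a bias row-wise to an n x k matrix (column-major recycling)
.addb <- function(P, b) P + rep(b, each = nrow(P))

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.dense_init <- function(n_in, n_out) list(W = .glorot(n_in, n_out), b = numeric(n_out))

# encoder: list of dense layers, all leaky-ReLU; last layer is the latent
.enc_init <- function(input_dim, widths, latent_dim) {
  sizes <- c(input_dim, widths, latent_dim)
  lapply(seq_len(length(sizes) - 1L), function(i) .dense_init(sizes[i], sizes[i + 1L]))
}

# decoder: hidden leaky-ReLU layers from the latent, then a tanh output layer
# whose input is the concatenation of the last hidden layer and the
# (dropout-processed) input vector — the skip connection.
.dec_init <- function(latent_dim, widths, output_dim) {
  sizes <- c(latent_dim, widths)
  hidden <- if (length(widths))
    lapply(seq_along(widths), function(i) .dense_init(sizes[i], sizes[i + 1L]))
  else list()
  last <- if (length(widths)) widths[length(widths)] else latent_dim
  list(hidden = hidden, out = .dense_init(last + output_dim, output_dim))
}

.enc_forward <- function(enc, X, alpha) {
  L <- length(enc)
  pres <- vector("list", L)
  acts <- vector("list", L)
  H <- X
  for (i in seq_len(L)) {
    P <- .addb(H %*% enc[[i]]$W, enc[[i]]$b)
    H <- .lrelu(P, alpha)
    pres[[i]] <- P
    acts[[i]] <- H
  }
  list(pres = pres, acts = acts, z = H)
}

.dec_forward <- function(dec, Z, Xskip, alpha) {
  L <- length(dec$hidden)
  pres <- vector("list", L)
  acts <- vector("list", L)
  H <- Z
  for (i in seq_len(L)) {
    P <- .addb(H %*% dec$hidden[[i]]$W, dec$hidden[[i]]$b)
    H <- .lrelu(P, alpha)
    pres[[i]] <- P
    acts[[i]] <- H
  }
  C <- cbind(H, Xskip)
  U <- .addb(C %*% dec$out$W, dec$out$b)
  list(pres = pres, acts = acts, C = C, U = U, Y = tanh(U))
}

# Backward pass from dL/dY through one decoder and (optionally) the encoder.
# `X` is the matrix that fed both the encoder and the skip path. Returns
# gradient trees mirroring the parameter trees, plus the input gradient when
# requested (sum of the skip-path and encoder-path contributions).
.net_backward <- function(enc, dec, X, fe, fd, dY, alpha, l1 = 0,
                          freeze_encoder = FALSE, want_input_grad = FALSE) {
  n <- nrow(X)
  G <- ncol(X)
  dU <- dY * (1 - fd$Y^2)
  g_out <- list(W = crossprod(fd$C, dU), b = colSums(dU))
  dC <- tcrossprod(dU, dec$out$W)
  hw <- ncol(fd$C) - G
  dH <- dC[, seq_len(hw), drop = FALSE]
  dXskip <- dC[, hw + seq_len(G), drop = FALSE]
  g_hidden <- vector("list", length(dec$hidden))
  for (i in rev(seq_along(dec$hidden))) {
    dP <- dH * .lrelu_g(fd$pres[[i]], alpha)
    inp <- if (i == 1L) fe$z else fd$acts[[i - 1L]]
    g_hidden[[i]] <- list(W = crossprod(inp, dP), b = colSums(dP))
    dH <- tcrossprod(dP, dec$hidden[[i]]$W)
  }
  dZ <- dH
  if (l1 > 0) dZ <- dZ + l1 * sign(fe$z) / n
  g_enc <- NULL
  dX <- NULL
  if (!freeze_encoder || want_input_grad) {
    g_enc <- vector("list", length(enc))
    dHe <- dZ
    for (i in rev(seq_along(enc))) {
      dP <- dHe * .lrelu_g(fe$pres[[i]], alpha)
      inp <- if (i == 1L) X else fe$acts[[i - 1L]]
      g_enc[[i]] <- list(W = crossprod(inp, dP), b = colSums(dP))
      dHe <- tcrossprod(dP, enc[[i]]$W)
    }
    dX <- dXskip + dHe
  }
  list(enc = g_enc, dec = list(hidden = g_hidden, out = g_out), dX = dX)
}

## ---- Adam ------------------------------------------------------------

.adam_state <- function(params) {
  if (is.numeric(params)) return(list(m = params * 0, v = params * 0))
  lapply(params, .adam_state)
}

# One Adam update over a parameter tree; returns list(p = params, s = state).
.adam_apply <- function(params, grads, state, lr, t,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.numeric(params)) {
    m <- b1 * state$m + (1 - b1) * grads
    v <- b2 * state$v + (1 - b2) * grads * grads
    p <- params - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    return(list(p = p, s = list(m = m, v = v)))
  }
  ps <- params
  ss <- state
  for (i in seq_along(params)) {
    r <- .adam_apply(params[[i]], grads[[i]], state[[i]], lr, t, b1, b2, eps)
    ps[[i]] <- r$p
    ss[[i]] <- r$s
  }
  list(p = ps, s = ss)
}

# inverted dropout: zero with prob `rate`, survivors scaled by 1/(1-rate)
.apply_dropout <- function(X, rate) {
  if (rate <= 0) return(X)
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  X * mask
}
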