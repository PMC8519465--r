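# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic entry points (training, simulation, optimizer init) route
# through this so that a seed argument fully determines the result without
# clobbering the user's RNG stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert <- function(cond, ...) if (!isTRUE(cond)) .stopf(...)

# Derive a child seed from a base seed, kept within 32-bit integer range.
.child_seed <- function(seed, i) as.integer((as.numeric(seed) * 97 + i * 1009) %% 2147483647)
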