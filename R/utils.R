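# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# wrap phase to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# run expr under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic 32-bit sub-seed derived from a master seed and a stream index
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587 + 1
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
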