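# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. A NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = ge, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent 32-bit sub-seeds from one master seed so that
# replicate-level work is reproducible regardless of evaluation order.
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n))
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) <= tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
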