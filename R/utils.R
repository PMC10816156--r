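# Internal helpers shared across modules.

# Deterministic per-component seed derived from one global seed, so that each
# stochastic component (generator, bootstrap, PRESSO simulations, ...) runs on
# its own named substream. Result always fits a 32-bit integer.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
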