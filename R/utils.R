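`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a specific RNG seed without disturbing the caller's RNG
# state. seed = NULL runs in the current state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic per-cell sub-seeds derived from one master seed, kept below
# 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}
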