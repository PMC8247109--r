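# Internal helpers: seeded evaluation and deterministic seed derivation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split one root seed into per-stage seeds, kept inside the 32-bit integer
# range. Stages are numbered so that every consumer of randomness draws from
# its own stream.
.derive_seed <- function(root_seed, stage) {
  s <- (as.numeric(root_seed) * 48271 + as.numeric(stage) * 7919) %% 2147483629
  as.integer(s) + 1L
}

.is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

.is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
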