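# Internal helpers shared across modules.

# Round-half-up (1.5 -> 2, 2.5 -> 3), unlike base round()'s banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls never perturb user RNG streams.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 101 * stream) %% 2147483629
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
}
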