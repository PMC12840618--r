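# Internal helpers.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All randomness in the package flows through this,
# so no function perturbs global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniform integer draw on [lo, hi] (vectorised, inclusive).
runif_int <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
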