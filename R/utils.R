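# Run code with a local, restorable RNG state so exported functions are
# deterministic given their `seed` argument without disturbing the caller.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
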