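# Shared internal helpers.

.ltdfit_env <- new.env(parent = emptyenv())

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All generator randomness flows through
# this so a single configured seed fixes every output.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Snap x to multiples of `step`, then clamp to [lo, hi] (also multiples).
.snap <- function(x, step, lo, hi) {
  pmin(pmax(round(x / step) * step, lo), hi)
}
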