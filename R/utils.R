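# Run an expression under a local RNG state; restores the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}
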