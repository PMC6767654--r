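# Seeding utilities: every stochastic operation takes an explicit seed and
# leaves the global RNG state untouched.  Per-sample seeds are derived
# deterministically from a base seed so Monte Carlo runs are bit-reproducible
# and embarrassingly parallel (any execution order gives identical output).

#' Derive a deterministic sub-seed
#'
#' Mixes a base seed with an index (sample number, substream id) into a new
#' seed in `[1, 2^31 - 2]` via a multiplicative congruential hash. Used to
#' give each Monte Carlo realization, and each independent substream within a
#' realization, its own reproducible RNG stream.
#'
#' @param base_seed integer base seed.
#' @param index non-negative integer index (vectorized).
#' @return integer vector of derived seeds.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.double(base_seed) %% m + 1) * 48271 %% m
  x <- (s + as.double(index) * 69621 + 12345) %% m
  x <- (x * 16807 + 2147483587) %% m
  as.integer(x %% (m - 2) + 1)
}

# evaluate expr with a local, seeded RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
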