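# Deterministic RNG plumbing shared by the simulators and sweep drivers.

# Derive a child seed from a master seed and a (block, replicate) counter.
# Linear-congruential mixing mod 2^31 - 1; all arithmetic stays below 2^53
# so the derivation is exact in doubles and identical across platforms.
# Distinct (block, replicate) pairs map to distinct seeds for
# replicate < 69621, far beyond any sweep used here.
derive_seed <- function(master, block, replicate) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  s <- (s * 48271) %% m
  s <- (s + as.numeric(block) * 69621 + as.numeric(replicate)) %% m
  s <- (s * 16807) %% m
  if (s == 0) s <- 1
  as.integer(s)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no save/restore).
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
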