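# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic generators in the
# package route their randomness through this so that no function touches
# global random state as a side effect.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shannon entropy in bits of a vector of non-negative weights.
shannon_bits <- function(w) {
  w <- w[w > 0]
  if (length(w) == 0L) return(0)
  p <- w / sum(w)
  -sum(p * log2(p))
}

# x log2 x with the 0 log 0 = 0 convention, on an already-normalized p.
plogp <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
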