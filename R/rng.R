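# Seed handling: run code under a fixed RNG state, restoring the caller's
# stream afterwards so library calls never perturb user-level randomness.

with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic per-identity uniforms for the annealing classifier: the draw
# for (seed, iteration, id, k) depends only on those values, never on call
# order, so permuting subvolumes (together with their ids) permutes the
# randomness identically. LCG/xor mixing in exact double arithmetic: all
# intermediate products stay below 2^53.

.m32 <- 4294967296

mix32 <- function(x) {
  x <- (x * 69069 + 1234567) %% .m32     # 69069 * 2^32 < 2^53: exact
  hi <- floor(x / 65536)
  lo <- x %% 65536
  x <- bitwXor(as.integer(lo), as.integer(hi)) + hi * 65536
  (x * 60493 + 390581) %% .m32
}

hash_uniform <- function(seed, iter, id, k = 1) {
  x <- (abs(seed) %% .m32)
  x <- mix32(x + iter)
  x <- mix32(x + id)
  x <- mix32(x + k)
  x <- mix32(x)
  (x + 0.5) / .m32
}
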