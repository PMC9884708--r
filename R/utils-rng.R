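# Internal RNG plumbing. Every user-facing stochastic entry point takes a
# `seed`; when non-NULL the global RNG state is saved, reseeded, and restored
# on exit, so callers get reproducibility without side effects on the
# session stream.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range. Deterministic and collision-poor for small indices.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1299721) %% 2147483647)
}
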