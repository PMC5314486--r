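# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from a parent seed and index keys.
# Keeps results for early genes stable when later genes are added, and stays
# below 2^31 (R integer range).
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) h <- (h * 1000003 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}
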