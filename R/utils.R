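# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic substream seed from (seed, tag): adding a draw to one stage
# of a pipeline must not shift the randomness of another stage
substream_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes) * 131) %% 999983
  as.integer((abs(as.numeric(seed)) %% 2147000000 + h) %% 2147483647)
}
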