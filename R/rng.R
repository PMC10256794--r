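# Deterministic per-stage substreams from one study-level seed.
# A small string hash keeps stages independent without extra dependencies;
# everything stays below 2^31 so seeds remain valid R integers.
derive_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# evaluate expr with a local RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
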