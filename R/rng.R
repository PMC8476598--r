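# Reproducibility helpers. Every stochastic step derives its own stream from
# (base seed, string key) so results do not depend on the order in which
# slides or stages are processed.

# FNV-1a style 32-bit string hash, folded into [0, 2^31 - 2].
hash32 <- function(key) {
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    lb <- h %% 256                     # xor only touches the low byte
    h <- h - lb + bitwXor(as.integer(lb), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 2654435761 + hash32(key)) %% 2147483647)
}

with_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  expr
}
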