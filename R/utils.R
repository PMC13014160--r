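## Run an expression under a local RNG state; the global stream is
## untouched. All stochastic components route their seeds through this so
## a master seed fixes every draw in a pipeline.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed and a stream index; stays within
## 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
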