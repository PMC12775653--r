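# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; `seed = NULL` keeps the current stream (still restoring nothing).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
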