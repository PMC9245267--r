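# internal helpers

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (no isolation).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stopf("'%s' must be %s %s (got %g)", name, if (strict) ">" else ">=", lower, x)
  invisible(x)
}
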