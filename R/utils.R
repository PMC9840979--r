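# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user
# randomness. seed = NULL runs expr under the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# run-length encoding of a logical vector as (value, length, start) rows
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, length = r$lengths,
             start = ends - r$lengths + 1L, end = ends)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
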