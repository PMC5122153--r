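# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit. With seed = NULL the current stream is
# used (and advanced) as usual.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seeds: one master seed, one offset per
# sub-generator, all kept inside 32-bit integer range.
split_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_proportion <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_(sprintf("'%s' must be a proportion in [0, 1]", name))
  invisible(x)
}
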