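#' @keywords internal
"_PACKAGE"

# Shared assertion helper: stop() with caller-friendly message, no call echo.
pg_stop <- function(...) stop(..., call. = FALSE)

pg_assert <- function(cond, ...) {
  if (!isTRUE(cond)) pg_stop(...)
  invisible(TRUE)
}

# Derive a child RNG seed from a base seed and a stream label, staying well
# below .Machine$integer.max so seeds survive as plain 32-bit integers.
derive_seed <- function(seed, stream) {
  pg_assert(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L + 1)
}

# Run an expression with a local RNG state so library code does not disturb
# the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
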