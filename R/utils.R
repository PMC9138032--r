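# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# seed = NULL means "use the current stream" (non-reproducible by design).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer, got %s", deparse(seed))
  }
  withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
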