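# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Small derived seeds for per-round / per-member streams, kept well inside
# 32-bit integer range whatever the user-facing seed is.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  as.integer(x)
}
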