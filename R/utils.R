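# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream of derived seeds, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Usage errors get their own condition class so the CLI can map them to
# a distinct exit status.
usage_error <- function(fmt, ...) {
  stop(structure(
    class = c("csanose_usage_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == as.integer(x)
}
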