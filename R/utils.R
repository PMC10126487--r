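# Internal validation helpers. All user-facing errors go through rlang::abort()
# with a class so callers (and the pipeline driver) can branch on them.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "facilinet_invalid_input", ...)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d (got %s)",
                         name, min, deparse(x)))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 || x > 1) {
    stop_invalid(sprintf("`%s` must be a single number in [0, 1] (got %s)",
                         name, deparse(x)))
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0) {
    stop_invalid(sprintf("`%s` must be a single non-negative number (got %s)",
                         name, deparse(x)))
  }
  as.numeric(x)
}

# Run `code` under a fixed RNG seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
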