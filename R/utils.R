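# Internal helpers: classed error conditions and seeded evaluation.

abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cogbattery_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number", "invalid_input")
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stream label, staying below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min), "invalid_input")
  }
  invisible(as.integer(x))
}
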