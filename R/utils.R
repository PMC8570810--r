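# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

# Clean a vector of node identifiers: character, trimmed, non-empty.
clean_ids <- function(x, what = "node identifier") {
  x <- trimws(as.character(x))
  if (any(is.na(x) | x == "")) {
    rlang::abort(sprintf("every %s must be a non-empty string", what))
  }
  x
}

# Derive independent child seeds from one integer seed, staying below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
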