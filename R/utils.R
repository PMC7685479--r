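#' @keywords internal
"_PACKAGE"

# Gene symbols are compared after uppercasing and whitespace-stripping,
# so MAF, expression and list files need not agree on case.
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

# Deterministic 31-bit hash of strings, used to derive independent RNG
# substreams for (cohort, gene) so per-gene runs are order-independent.
hash31 <- function(...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647L
  as.integer(h)
}

# Combine a user seed with a string context into a reproducible substream
# seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  as.integer((as.numeric(seed) %% 2147483647 + hash31(...)) %% 2147483647)
}

ds_message <- function(...) message("[driverscan] ", ...)

# Condition constructors: the pipeline consumes these rather than crashing.
untestable_condition <- function(msg) {
  structure(class = c("sam_untestable", "condition"),
            list(message = msg, call = NULL))
}

no_eligible_samples_condition <- function(msg) {
  structure(class = c("no_eligible_samples", "condition"),
            list(message = msg, call = NULL))
}
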