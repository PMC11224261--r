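## Internal helpers shared across modules.

# Fan a single user-facing seed out to named substreams so that, e.g., the
# permutation stage is reproducible independently of how many simulation
# draws preceded it. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(simulate = 1L, permute = 2L, community = 3L, analyze = 4L,
               generic = 5L)
  k <- offsets[[match.arg(stream, names(offsets))]]
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483647)
}

# stop() with a consistent header so callers/tests can match on error class.
coreact_stop <- function(..., class = "coreact_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

validation_stop <- function(...) coreact_stop(..., class = "coreact_validation_error")
schema_stop <- function(...) coreact_stop(..., class = "coreact_schema_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
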